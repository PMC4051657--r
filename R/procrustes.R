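#' Optimal least-squares rotation between two centered configurations
#'
#' Solves the orthogonal Procrustes problem restricted to proper rotations:
#' the 3 x 3 rotation `R` (determinant +1) minimizing
#' `||source %*% R - target||` in the Frobenius norm. Reflections are never
#' returned, so the handedness of the source configuration is preserved; when
#' the unconstrained optimum is a reflection, the sign of the smallest
#' singular direction is flipped (the standard determinant correction).
#'
#' @param source,target k x 3 matrices, both centered at the origin, k >= 3.
#' @return 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(source, target) {
  stopifnot(is.matrix(source), is.matrix(target),
            ncol(source) == 3L, all(dim(source) == dim(target)),
            nrow(source) >= 3L)
  s <- crossprod(source, target)            # 3 x 3 cross-covariance
  sv <- svd(s)
  if (sum(sv$d > max(sv$d[1L], .Machine$double.eps) * 1e-12) < 2L) {
    warn_("degenerate configuration (rank < 2); returning identity rotation")
    return(diag(3))
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Full Procrustes superimposition of a set of configurations: each is
#' centered and scaled to unit centroid size, then iteratively rotated to the
#' current consensus (the coordinate-wise mean of the aligned set) until the
#' root-mean-square change of the consensus falls below `tol`.
#'
#' @param x a [landmark_array()] with at least 2 configurations.
#' @param tol convergence tolerance on the RMS change of the consensus
#'   between iterations. Default 1e-10.
#' @param max_iter maximum number of iterations. Default 100.
#' @return An object of class `gpa` with elements `aligned` (landmark array,
#'   unit centroid size, consensus orientation), `consensus` (k x 3 mean
#'   shape), `centroid_sizes`, `iterations`, `converged`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(x, "landmark_array"))
  n <- n_individuals(x)
  if (n < 2L) stop_("generalized Procrustes analysis needs >= 2 configurations")
  k <- dim(x)[1L]
  a <- unclass(x)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    m <- center_config(a[, , i])
    sizes[i] <- sqrt(sum(m^2))
    if (sizes[i] <= 0) stop_("configuration ", i, " has zero centroid size")
    a[, , i] <- m / sizes[i]
  }
  consensus <- a[, , 1L]
  converged <- FALSE
  iter <- 0L
  objective <- numeric()
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      a[, , i] <- a[, , i] %*% optimal_rotation(a[, , i], consensus)
    new_consensus <- apply(a, c(1L, 2L), mean)
    objective[iter] <- sum(sweep(a, c(1L, 2L), new_consensus)^2)
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn_("GPA did not converge in ", max_iter, " iterations")
  dimnames(consensus) <- dimnames(x)[1:2]
  structure(
    list(aligned = landmark_array(a, ids = dimnames(x)[[3L]],
                                  landmark_names = dimnames(x)[[1L]]),
         consensus = consensus,
         centroid_sizes = stats::setNames(sizes, dimnames(x)[[3L]]),
         iterations = iter, converged = converged, objective = objective),
    class = "gpa"
  )
}

#' @export
print.gpa <- function(x, ...) {
  cat("Generalized Procrustes fit:", n_individuals(x$aligned),
      "configurations,", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

## rotate an aligned ensemble (and consensus) so the consensus best matches a
## reference configuration; used to express results in a template's frame
orient_gpa <- function(fit, reference) {
  ref <- center_config(reference)
  ref <- ref / sqrt(sum(ref^2))
  r <- optimal_rotation(center_config(fit$consensus), ref)
  a <- unclass(fit$aligned)
  for (i in seq_len(dim(a)[3L])) a[, , i] <- a[, , i] %*% r
  fit$aligned <- landmark_array(a, ids = dimnames(a)[[3L]],
                                landmark_names = dimnames(a)[[1L]])
  fit$consensus <- fit$consensus %*% r
  dimnames(fit$consensus) <- dimnames(reference) %||% dimnames(fit$consensus)
  fit
}
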