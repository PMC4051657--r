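#' Reflect and relabel a configuration
#'
#' Builds the mirror copy used by the object-symmetry decomposition: the
#' reflection-axis coordinate is negated for every landmark, then the left and
#' right labels within each bilateral pair are swapped (midline landmarks keep
#' their labels). Applying the operation twice returns the input exactly.
#'
#' @param x a k x 3 matrix or a [landmark_array()].
#' @param scheme a [symmetry_scheme()] covering all k landmarks.
#' @return Object of the same type as `x`.
#' @export
reflect_relabel <- function(x, scheme = face_scheme()) {
  if (inherits(x, "landmark_array")) {
    a <- unclass(x)
    for (i in seq_len(dim(a)[3L]))
      a[, , i] <- reflect_relabel(a[, , i], scheme)
    return(landmark_array(a, ids = dimnames(x)[[3L]],
                          landmark_names = dimnames(x)[[1L]]))
  }
  stopifnot(is.matrix(x), ncol(x) == 3L)
  if (nrow(x) != scheme$n_landmarks)
    stop_("scheme covers ", scheme$n_landmarks, " landmarks but configuration has ",
          nrow(x))
  y <- x
  y[, scheme$reflect_axis] <- -y[, scheme$reflect_axis]
  perm <- seq_len(nrow(x))
  perm[scheme$pairs[, 1L]] <- scheme$pairs[, 2L]
  perm[scheme$pairs[, 2L]] <- scheme$pairs[, 1L]
  y <- y[perm, , drop = FALSE]
  rownames(y) <- rownames(x)
  y
}

#' Object-symmetry asymmetry scores
#'
#' Decomposes landmark asymmetry into directional and fluctuating components.
#' A reflected-relabeled copy of every configuration is built and a single
#' generalized Procrustes analysis is run jointly over all 2n configurations.
#' Each individual's asymmetry vector is the difference between its aligned
#' original and aligned reflected copy, flattened to length 3k:
#' \describe{
#'   \item{TA}{total asymmetry, `ta_i = ||a_i||` -- the Procrustes-space
#'     distance between the individual's configuration and its reflection.}
#'   \item{DA}{directional asymmetry, the population mean asymmetry vector
#'     `mean(a_i)`, reported as a vector and as its magnitude.}
#'   \item{FA}{fluctuating asymmetry, `fa_i = ||a_i - mean(a)||` -- the
#'     individual's deviation from the population asymmetry pattern.}
#' }
#' Scores are Euclidean norms in the joint-GPA aligned coordinate space
#' (small-deviation Procrustes distances); no tangent-space projection is
#' applied beyond the alignment itself.
#'
#' @param x a [landmark_array()], n >= 2 individuals (n = 1 allowed only with
#'   `ta_only = TRUE`; FA is undefined for a single individual).
#' @param scheme a [symmetry_scheme()].
#' @param orient_to optional k x 3 reference configuration; the aligned
#'   ensemble is rotated so the consensus best matches it (useful to express
#'   the DA vector in a template's frame).
#' @param ta_only if TRUE, only TA is computed and n = 1 is permitted.
#' @param tol,max_iter GPA controls, see [gpa()].
#' @return Object of class `asymmetry_scores`: list with `individual_ids`,
#'   `ta`, `fa`, `da_vector` (k x 3 matrix), `da_magnitude`, `asym` (n x 3k
#'   matrix of per-individual asymmetry vectors), `gpa` (the joint fit).
#' @export
asymmetry_scores <- function(x, scheme = face_scheme(), orient_to = NULL,
                             ta_only = FALSE, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(x, "landmark_array"))
  n <- n_individuals(x)
  if (n < 2L && !ta_only)
    stop_("FA is undefined for a single individual; use ta_only = TRUE for TA")
  ids <- dimnames(x)[[3L]]
  refl <- reflect_relabel(x, scheme)
  both <- array(c(unclass(x), unclass(refl)), dim = c(dim(x)[1:2], 2L * n))
  joint <- landmark_array(both, ids = c(ids, paste0(ids, ".refl")),
                          landmark_names = dimnames(x)[[1L]])
  fit <- gpa(joint, tol = tol, max_iter = max_iter)
  if (!is.null(orient_to)) fit <- orient_gpa(fit, orient_to)
  a <- unclass(fit$aligned)
  k3 <- prod(dim(x)[1:2])
  asym <- matrix(0, n, k3)
  for (i in seq_len(n))
    asym[i, ] <- as.vector(a[, , i] - a[, , n + i])
  rownames(asym) <- ids
  ta <- sqrt(rowSums(asym^2))
  da <- colMeans(asym)
  if (ta_only && n < 2L) {
    fa <- NA_real_
    da_vec <- matrix(asym[1L, ], dim(x)[1L], 3L)
  } else {
    fa <- sqrt(rowSums(sweep(asym, 2L, da)^2))
    da_vec <- matrix(da, dim(x)[1L], 3L)
  }
  dimnames(da_vec) <- dimnames(x)[1:2]
  structure(
    list(individual_ids = ids,
         ta = stats::setNames(ta, ids),
         fa = stats::setNames(fa, ids),
         da_vector = da_vec,
         da_magnitude = sqrt(sum(da_vec^2)),
         asym = asym,
         gpa = fit),
    class = "asymmetry_scores"
  )
}

#' @export
print.asymmetry_scores <- function(x, digits = 4, ...) {
  cat("Asymmetry scores for", length(x$ta), "individuals\n")
  cat("  mean TA:", signif(mean(x$ta), digits),
      " mean FA:", signif(mean(x$fa), digits),
      " DA magnitude:", signif(x$da_magnitude, digits), "\n")
  invisible(x)
}

#' @export
plot.asymmetry_scores <- function(x, y = NULL, ...) {
  if (is.null(y)) {
    plot(x$ta, x$fa, xlab = "Total asymmetry (TA)",
         ylab = "Fluctuating asymmetry (FA)", ...)
  } else {
    plot(y, x$fa, xlab = deparse(substitute(y)),
         ylab = "Fluctuating asymmetry (FA)", ...)
    graphics::abline(stats::lm(x$fa ~ y), lty = 2)
  }
  invisible(x)
}

#' @export
as.data.frame.asymmetry_scores <- function(x, ...) {
  data.frame(individual_id = x$individual_ids, ta = unname(x$ta),
             fa = unname(x$fa), stringsAsFactors = FALSE)
}
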