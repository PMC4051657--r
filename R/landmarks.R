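#' Collection of landmark configurations
#'
#' Container for a set of individuals' landmark configurations: a
#' k x 3 x n array with landmark names, coordinate names (x, y, z) and
#' individual ids as dimnames. All coordinates must be finite and every
#' configuration must carry the same landmarks in the same order.
#'
#' @param coords k x 3 x n numeric array, or a list of k x 3 matrices.
#' @param ids character vector of n individual ids (unique).
#' @param landmark_names character vector of k landmark names.
#' @return An object of class `landmark_array`.
#' @export
landmark_array <- function(coords, ids = NULL,
                           landmark_names = face_landmarks()) {
  if (is.list(coords)) {
    ids <- ids %||% names(coords)
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  k <- dim(coords)[1L]
  n <- dim(coords)[3L]
  if (length(landmark_names) != k)
    stop_("need exactly one name per landmark (got ", length(landmark_names),
          " names for ", k, " landmarks)")
  ids <- as.character(ids %||% sprintf("ind%04d", seq_len(n)))
  if (length(ids) != n) stop_("need one id per configuration")
  if (anyDuplicated(ids)) stop_("duplicate individual ids")
  if (!all(is.finite(coords))) stop_("non-finite landmark coordinates")
  dimnames(coords) <- list(landmark_names, c("x", "y", "z"), ids)
  structure(coords, class = "landmark_array")
}

#' @export
print.landmark_array <- function(x, ...) {
  d <- dim(x)
  cat("Landmark array:", d[3L], "individuals x", d[1L], "landmarks (3D)\n")
  invisible(x)
}

#' @export
`[.landmark_array` <- function(x, i, ...) {
  y <- unclass(x)[, , i, drop = FALSE]
  landmark_array(y, ids = dimnames(y)[[3L]], landmark_names = dimnames(y)[[1L]])
}

n_individuals <- function(x) dim(x)[3L]

config_of <- function(x, i) {
  m <- unclass(x)[, , i]
  dim(m) <- dim(x)[1:2]
  dimnames(m) <- dimnames(x)[1:2]
  m
}
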