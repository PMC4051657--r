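#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the standard size measure removed by full Procrustes
#' superimposition.
#'
#' @param x k x 3 numeric matrix of landmark coordinates.
#' @return A positive scalar.
#' @export
centroid_size <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 3L)
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2L, ctr)^2))
}

## center a k x 3 configuration at the origin
center_config <- function(x) sweep(x, 2L, colMeans(x))

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0
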