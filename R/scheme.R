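#' Bilateral symmetry scheme for a landmark configuration
#'
#' Describes the object-symmetry structure of a landmark set: which landmarks
#' form left/right mirror pairs, which lie on the midline, and which
#' coordinate axis is flipped by the reflection. Every landmark index must
#' appear exactly once across the pairs and the midline.
#'
#' @param pairs two-column integer matrix (or list of length-2 vectors); each
#'   row is a (left, right) pair of landmark indices.
#' @param midline integer vector of midline landmark indices.
#' @param reflect_axis which coordinate axis (1 = x, 2 = y, 3 = z) is negated
#'   by the reflection. Default 1.
#' @param landmark_names optional character vector naming all landmarks, in
#'   canonical order.
#' @return An object of class `symmetry_scheme`.
#' @examples
#' face_scheme()
#' @export
symmetry_scheme <- function(pairs, midline, reflect_axis = 1L,
                            landmark_names = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  reflect_axis <- as.integer(reflect_axis)
  stopifnot(reflect_axis %in% 1:3)
  idx <- c(as.vector(pairs), midline)
  k <- length(idx)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(k)))
    stop_("each landmark index must appear exactly once across pairs and midline")
  if (!is.null(landmark_names) && length(landmark_names) != k)
    stop_("landmark_names must have one name per landmark index")
  structure(
    list(pairs = pairs, midline = midline, reflect_axis = reflect_axis,
         n_landmarks = k, landmark_names = landmark_names),
    class = "symmetry_scheme"
  )
}

#' @export
print.symmetry_scheme <- function(x, ...) {
  cat("Symmetry scheme:", nrow(x$pairs), "bilateral pairs,",
      length(x$midline), "midline landmarks; reflection axis",
      c("x", "y", "z")[x$reflect_axis], "\n")
  if (!is.null(x$landmark_names)) {
    for (i in seq_len(nrow(x$pairs)))
      cat("  pair:   ", x$landmark_names[x$pairs[i, 1L]], "<->",
          x$landmark_names[x$pairs[i, 2L]], "\n")
    cat("  midline:", paste(x$landmark_names[x$midline], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Canonical mid-facial landmark names
#'
#' The nine mid-facial landmarks used throughout the package, in canonical
#' order: Zygion (left/right), Alare (left/right), eyeball centers
#' (left/right), then the midline points Nasion, Pronasale, Subnasale.
#'
#' @return Character vector of length 9.
#' @export
face_landmarks <- function() {
  c("zygion_l", "zygion_r", "alare_l", "alare_r", "eyeball_l", "eyeball_r",
    "nasion", "pronasale", "subnasale")
}

#' Default mid-facial symmetry scheme
#'
#' Three bilateral pairs (Zygion, Alare, eyeball centers) and three midline
#' landmarks (Nasion, Pronasale, Subnasale); the midsagittal plane is x = 0,
#' so the reflection negates the x coordinate.
#'
#' @return A [symmetry_scheme()].
#' @export
face_scheme <- function() {
  symmetry_scheme(
    pairs = rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)),
    midline = 7:9,
    reflect_axis = 1L,
    landmark_names = face_landmarks()
  )
}

#' Symmetric template face
#'
#' A bilaterally symmetric 9-landmark mid-facial template (anatomically
#' plausible proportions), centered at the origin and scaled to unit centroid
#' size. x is the left-right axis (midsagittal plane x = 0), y vertical,
#' z anterior depth.
#'
#' @return 9 x 3 numeric matrix with landmark row names.
#' @export
face_template <- function() {
  tpl <- rbind(
    zygion_l  = c( 65, -10, -40),
    zygion_r  = c(-65, -10, -40),
    alare_l   = c( 17, -38,   8),
    alare_r   = c(-17, -38,   8),
    eyeball_l = c( 32,   2, -18),
    eyeball_r = c(-32,   2, -18),
    nasion    = c(  0,  10,   0),
    pronasale = c(  0, -30,  25),
    subnasale = c(  0, -45,  12)
  )
  colnames(tpl) <- c("x", "y", "z")
  tpl <- center_config(tpl)
  tpl / centroid_size(tpl)
}

## max abs deviation of a configuration from exact symmetry under a scheme
symmetry_residual <- function(x, scheme) {
  r <- reflect_relabel(x, scheme)
  max(abs(r - x))
}
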