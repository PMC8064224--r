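# B-scan augmentation transforms used when training interface segmenters on
# small data sets. Images are depth x width matrices: rows index depth along
# the A-scan, columns index A-scans across the B-scan.

#' Sinusoidal circular shift of A-scans across a B-scan
#'
#' Circularly shifts column `j` (0-based) of the image along depth by
#' `round(amplitude * sin(2 * pi * frequency * j / width + phase))` pixels.
#' Each column's pixel multiset is preserved, and negating the amplitude with
#' the same phase restores the original image.
#'
#' @param bscan_image numeric matrix (depth x width).
#' @param amplitude shift amplitude in pixels, `>= 0` (a negative amplitude is
#'   accepted as the explicit inverse transform).
#' @param frequency cycles per B-scan width.
#' @param phase phase in radians.
#' @return matrix of the same dimensions.
#' @export
#' @examples
#' img <- matrix(seq_len(20), 5, 4)
#' identical(sinusoid_augment(img, 0, 1, 0), img)
sinusoid_augment <- function(bscan_image, amplitude, frequency, phase = 0) {
  stopifnot(is.matrix(bscan_image))
  if (!is.finite(amplitude)) stop("amplitude must be finite", call. = FALSE)
  d <- nrow(bscan_image)
  w <- ncol(bscan_image)
  if (d == 0L || w == 0L) return(bscan_image)
  j <- seq_len(w) - 1L
  shift <- round(amplitude * sin(2 * pi * frequency * j / w + phase))
  out <- bscan_image
  for (col in seq_len(w)) {
    s <- shift[col] %% d
    if (s != 0) out[, col] <- bscan_image[c((d - s + 1L):d, 1L:(d - s)), col]
  }
  out
}

#' Horizontal mirror of a B-scan
#'
#' Reverses the A-scan (column) order; applying it twice restores the input.
#'
#' @param bscan_image numeric matrix (depth x width).
#' @return mirrored matrix.
#' @export
mirror_augment <- function(bscan_image) {
  stopifnot(is.matrix(bscan_image))
  if (ncol(bscan_image) <= 1L) return(bscan_image)
  bscan_image[, ncol(bscan_image):1L, drop = FALSE]
}
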