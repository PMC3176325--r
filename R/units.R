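#' Viewing-geometry unit conversions
#'
#' The stimulus array is a 496 x 496 pixel raster subtending 14 degrees of
#' visual angle at the modelled viewing distance, so 1 degree = 496/14 px
#' and 1 arcmin = 496/840 px. All placement distances are stored in pixels
#' and converted to arcmin only for the density criterion, which the field
#' states in arcmin.
#'
#' @param px,arcmin,deg quantities to convert.
#' @param array_side array side length in pixels.
#' @param array_deg visual angle subtended by the array, in degrees.
#' @return the converted quantity (numeric).
#' @name units
NULL

#' @rdname units
#' @export
px_per_deg <- function(array_side = 496, array_deg = 14) array_side / array_deg

#' @rdname units
#' @export
px_per_arcmin <- function(array_side = 496, array_deg = 14) {
  px_per_deg(array_side, array_deg) / 60
}

#' @rdname units
#' @export
px_to_arcmin <- function(px, array_side = 496, array_deg = 14) {
  px / px_per_arcmin(array_side, array_deg)
}

#' @rdname units
#' @export
arcmin_to_px <- function(arcmin, array_side = 496, array_deg = 14) {
  arcmin * px_per_arcmin(array_side, array_deg)
}

# circular distance between orientations with period 180 degrees
circ_dist180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
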