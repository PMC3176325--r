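#' Assign condition-specific orientations to an element field
#'
#' The four array types of the 2x2 design differ only in element
#' orientations:
#' * no-contour / iso: every element shares one orientation;
#' * no-contour / random: every element i.i.d. uniform on `[0, 180)`;
#' * contour / iso: contour elements parallel to their local tangent,
#'   all surround elements share one orientation;
#' * contour / random: contour elements tangent-parallel, surround
#'   elements i.i.d. uniform.
#'
#' The shared iso orientation is drawn uniformly at random per array.
#'
#' @param field an `element_field`.
#' @param condition list or character; either `list(contour =, context =)`
#'   or one of `"contour/iso"`, `"contour/random"`, `"no-contour/iso"`,
#'   `"no-contour/random"`.
#' @param sampling the `contour_sampling` whose tangents the contour
#'   elements adopt (required for contour conditions).
#' @param seed integer seed.
#' @return a `gabor_array`: the field tibble gaining an `orientation`
#'   column (degrees in `[0, 180)`), with attributes `condition`,
#'   `iso_orientation` (NA for random context) and those of the field.
#' @export
assign_orientations <- function(field, condition, sampling = NULL, seed = 1) {
  stopifnot(inherits(field, "element_field"))
  cond <- parse_condition(condition)
  set.seed(seed)
  n <- nrow(field)
  is_contour <- field$region == "contour"
  orientation <- numeric(n)
  iso <- NA_real_
  if (cond$context == "iso") {
    iso <- stats::runif(1, 0, 180)
    orientation[] <- iso
  } else {
    orientation <- stats::runif(n, 0, 180)
  }
  if (cond$contour) {
    if (is.null(sampling)) stop("contour conditions need `sampling` tangents")
    if (sum(is_contour) != nrow(sampling)) {
      stop("field and sampling disagree on the number of contour elements")
    }
    orientation[is_contour] <- sampling$tangent
  }
  out <- field
  out$orientation <- orientation %% 180
  attr(out, "condition") <- cond
  attr(out, "iso_orientation") <- iso
  class(out) <- c("gabor_array", class(field))
  out
}

parse_condition <- function(condition) {
  if (is.character(condition)) {
    parts <- strsplit(condition, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% c("contour", "no-contour") ||
        !parts[2] %in% c("iso", "random")) {
      stop("unknown condition label: ", condition)
    }
    condition <- list(contour = parts[1] == "contour", context = parts[2])
  }
  stopifnot(is.logical(condition$contour),
            condition$context %in% c("iso", "random"))
  condition
}

#' Re-randomize orientations of a no-contour array
#'
#' Successive no-contour arrays reuse the same element positions but every
#' element is rotated at least `min_rotation` degrees away from its
#' previous orientation (circular distance with period 180). New
#' orientations are rejection-sampled uniformly on the allowed set, so the
#' accepted values are uniform on `[0,180)` minus the exclusion band
#' around the previous orientation.
#'
#' @param prev a no-contour `gabor_array`.
#' @param seed integer seed.
#' @param min_rotation minimum circular orientation change, degrees.
#' @return a `gabor_array` with identical positions and new orientations.
#' @export
rerandomize_orientations <- function(prev, seed, min_rotation = 25) {
  stopifnot(inherits(prev, "gabor_array"))
  cond <- attr(prev, "condition")
  if (isTRUE(cond$contour)) stop("re-randomization applies to no-contour arrays")
  stopifnot(min_rotation < 90)
  set.seed(seed)
  old <- prev$orientation
  new <- stats::runif(length(old), 0, 180)
  bad <- circ_dist180(new, old) < min_rotation
  while (any(bad)) {
    new[bad] <- stats::runif(sum(bad), 0, 180)
    bad <- circ_dist180(new, old) < min_rotation
  }
  out <- prev
  out$orientation <- new
  attr(out, "condition") <- list(contour = FALSE, context = "random")
  attr(out, "iso_orientation") <- NA_real_
  out
}

#' Render a Gabor array to a greyscale raster
#'
#' Each element is the product of a cosine luminance grating (4 cycles per
#' degree; period about 8.86 px at 496 px = 14 deg) and an isotropic
#' Gaussian envelope (SD 4 arcmin, about 2.36 px), composited additively
#' on a mid-grey background in floating point, then quantized to 8-bit.
#' The carrier phase is random per element (seeded) so that no luminance
#' artifact cues the contour. The envelope is truncated at ±3 SD; pixels
#' farther than that from every element center stay exactly at background.
#' Catch stimuli get a thin dark circle outline at a uniform-random,
#' fully contained location.
#'
#' @param gabors a `gabor_array`.
#' @param px_per_deg pixels per degree of visual angle.
#' @param sf_cpd carrier spatial frequency, cycles/degree.
#' @param sd_arcmin envelope SD, arcmin.
#' @param contrast Michelson contrast of each element.
#' @param background background grey level (0..255).
#' @param catch logical; overlay a catch circle.
#' @param catch_radius_deg catch-circle radius, degrees.
#' @param seed seed for carrier phases and catch position.
#' @param phases optional per-element carrier phases (radians),
#'   overriding the random default; recycled to the element count.
#' @return numeric matrix `array_side` x `array_side` of integer grey
#'   levels in 0..255 (row = y, column = x, row 1 at y = 0); attributes
#'   `catch_center`, `catch_radius` (px) when `catch = TRUE`, and
#'   `clipped` (count of elements whose ±3 SD support crossed the
#'   border and was clipped).
#' @export
render_array <- function(gabors, px_per_deg = 496 / 14, sf_cpd = 4,
                         sd_arcmin = 4, contrast = 0.9, background = 128,
                         catch = FALSE, catch_radius_deg = 0.5, seed = 1,
                         phases = NULL) {
  stopifnot(inherits(gabors, "gabor_array"))
  set.seed(seed)
  side <- attr(gabors, "array_side")
  sd_px <- sd_arcmin * px_per_deg / 60
  period <- px_per_deg / sf_cpd
  amp <- contrast * background
  half <- ceiling(3 * sd_px)
  img <- matrix(0, side, side)
  if (is.null(phases)) phases <- stats::runif(nrow(gabors), 0, 2 * pi)
  phases <- rep_len(phases, nrow(gabors))
  n_clipped <- 0L
  for (i in seq_len(nrow(gabors))) {
    cx <- gabors$x[i]; cy <- gabors$y[i]
    ori <- gabors$orientation[i] * pi / 180
    if (floor(cx) - half < 0 || ceiling(cx) + half > side - 1 ||
        floor(cy) - half < 0 || ceiling(cy) + half > side - 1) {
      n_clipped <- n_clipped + 1L
    }
    xr <- max(0L, floor(cx) - half):min(side - 1L, ceiling(cx) + half)
    yr <- max(0L, floor(cy) - half):min(side - 1L, ceiling(cy) + half)
    dx <- outer(rep(1, length(yr)), xr - cx)
    dy <- outer(yr - cy, rep(1, length(xr)))
    r2 <- dx^2 + dy^2
    env <- exp(-r2 / (2 * sd_px^2))
    env[r2 > (3 * sd_px)^2] <- 0
    # carrier varies along the axis perpendicular to the element orientation
    u <- -dx * sin(ori) + dy * cos(ori)
    patch <- env * cos(2 * pi * u / period + phases[i])
    img[yr + 1L, xr + 1L] <- img[yr + 1L, xr + 1L] + patch
  }
  img <- background + amp * img
  out <- round(pmin(pmax(img, 0), 255))
  attr(out, "clipped") <- n_clipped
  if (catch) {
    rad <- catch_radius_deg * px_per_deg
    ctr <- stats::runif(2, rad + 2, side - rad - 2)
    xs <- outer(rep(1, side), 0:(side - 1)) - ctr[1]
    ys <- outer(0:(side - 1), rep(1, side)) - ctr[2]
    ring <- abs(sqrt(xs^2 + ys^2) - rad) <= 1
    out[ring] <- 0
    attr(out, "catch_center") <- ctr
    attr(out, "catch_radius") <- rad
  }
  class(out) <- c("gabor_image", class(out))
  out
}

#' Write a rendered array as an 8-bit greyscale PNG
#'
#' @param image a `gabor_image` matrix (grey levels 0..255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_array_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
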