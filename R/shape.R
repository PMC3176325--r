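#' Generate a closed radial-frequency shape outline
#'
#' A radial-frequency (RF) shape is a closed contour whose radius varies
#' sinusoidally with polar angle. Summing several RF components with random
#' integer frequencies and random phases produces the smooth blob-like
#' outlines used in contour-integration displays. The radius function is
#'
#'   r(theta) = R0 + sum_i a_i * sin(f_i * theta + phi_i)
#'
#' with five components. Frequencies are drawn without replacement from the
#' integers 2..8, amplitudes uniformly from `[0, amplitude_bound]`, and
#' phases uniformly from `[0, 2*pi)`. Outlines whose radius ever drops to
#' zero or below are rejected and resampled: a strictly positive
#' single-valued radius guarantees the curve is simple (non-self-
#' intersecting).
#'
#' @param seed integer seed; the same seed reproduces the identical shape.
#' @param base_radius mean radius R0 in pixels.
#' @param amplitude_bound upper bound for component amplitudes (px). The
#'   default 0.35 * base_radius keeps rejection rare while allowing marked
#'   deviations from circularity.
#' @param n_components number of RF components (default 5).
#' @param n_dense number of dense boundary samples in the stored polyline.
#' @param max_attempts resampling attempts before giving up (an error here
#'   signals an infeasible `amplitude_bound`).
#' @return an object of class `rf_shape`: list with `base_radius`,
#'   `components` (tibble: frequency, amplitude, phase), `center` (x, y)
#'   and `polyline` (n_dense x 2 matrix of x, y px; closed implicitly, the
#'   first vertex is not repeated).
#' @export
generate_rf_outline <- function(seed, base_radius = 100,
                                amplitude_bound = 0.35 * base_radius,
                                n_components = 5, n_dense = 4096,
                                max_attempts = 200) {
  stopifnot(base_radius > 0, amplitude_bound >= 0, n_components >= 1)
  set.seed(seed)
  theta <- seq(0, 2 * pi, length.out = n_dense + 1)[-(n_dense + 1)]
  for (attempt in seq_len(max_attempts)) {
    comps <- tibble::tibble(
      frequency = sample(2:8, n_components, replace = FALSE),
      amplitude = stats::runif(n_components, 0, amplitude_bound),
      phase     = stats::runif(n_components, 0, 2 * pi)
    )
    r <- rf_radius(base_radius, comps, theta)
    if (min(r) > 0) {
      shape <- structure(
        list(
          base_radius = base_radius,
          components  = comps,
          center      = c(0, 0),
          polyline    = cbind(x = r * cos(theta), y = r * sin(theta))
        ),
        class = "rf_shape"
      )
      return(shape)
    }
  }
  stop("could not generate a valid outline after ", max_attempts,
       " attempts; lower `amplitude_bound`")
}

#' Evaluate the RF radius function
#'
#' @param base_radius mean radius (px).
#' @param components tibble with columns frequency, amplitude, phase.
#' @param theta polar angles (radians).
#' @return radii at `theta` (px).
#' @export
rf_radius <- function(base_radius, components, theta) {
  r <- rep(base_radius, length(theta))
  for (i in seq_len(nrow(components))) {
    r <- r + components$amplitude[i] *
      sin(components$frequency[i] * theta + components$phase[i])
  }
  r
}

# signed shoelace area of a closed polyline (first vertex not repeated)
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# centroid of the uniform lamina enclosed by a closed polyline
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Rescale a shape to a fixed fraction of the array area and center it
#'
#' The enclosed polygon is scaled so that its area equals
#' `area_fraction * array_side^2` (default one eighth of a 496 px array)
#' and translated so that its center of mass (centroid of the uniform
#' lamina, not the mean of boundary points) coincides with the array
#' center.
#'
#' @param shape an `rf_shape`.
#' @param array_side array side length in px.
#' @param area_fraction target enclosed area as a fraction of
#'   `array_side^2`.
#' @return the transformed `rf_shape`; `base_radius` and component
#'   amplitudes are scaled consistently and `center` records the array
#'   center.
#' @export
rescale_and_center <- function(shape, array_side = 496, area_fraction = 1 / 8) {
  stopifnot(inherits(shape, "rf_shape"))
  target <- area_fraction * array_side^2
  a <- abs(polygon_area(shape$polyline))
  s <- sqrt(target / a)
  poly <- shape$polyline * s
  ctr <- polygon_centroid(poly)
  dest <- c(array_side / 2, array_side / 2)
  poly <- sweep(poly, 2, ctr - dest)
  shape$polyline <- poly
  shape$base_radius <- shape$base_radius * s
  shape$components$amplitude <- shape$components$amplitude * s
  shape$center <- dest
  shape
}

#' Sample equidistant points (with tangents) along a shape outline
#'
#' Places `n_points` positions at equal arc-length spacing along the
#' boundary (arc length measured by cumulative chord length on the dense
#' polyline) and returns the local tangent orientation at each, in degrees
#' modulo 180. These are the anchor positions and orientations of the
#' contour Gabor elements.
#'
#' @param shape a rescaled, centered `rf_shape`.
#' @param n_points number of boundary samples (default 45).
#' @return a tibble of class `contour_sampling` with columns `x`, `y`
#'   (px) and `tangent` (degrees in `[0, 180)`), and attribute
#'   `arc_spacing` (px).
#' @export
sample_contour_points <- function(shape, n_points = 45) {
  stopifnot(inherits(shape, "rf_shape"))
  if (n_points < 3) stop("`n_points` must be at least 3")
  poly <- shape$polyline
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  seg <- poly[nxt, , drop = FALSE] - poly
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))        # length n + 1, cum[n+1] = perimeter
  perim <- cum[n + 1]
  s <- (seq_len(n_points) - 1) * perim / n_points
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[idx]) / seglen[idx]
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  tang <- (atan2(seg[idx, 2], seg[idx, 1]) * 180 / pi) %% 180
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2], tangent = tang)
  attr(out, "arc_spacing") <- perim / n_points
  class(out) <- c("contour_sampling", class(out))
  out
}
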