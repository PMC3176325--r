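#' Populate the array with nonoverlapping Gabor element positions
#'
#' Dart-throwing (hard-core rejection) placement: the 45 contour positions
#' are kept exactly, then interior and exterior counts are drawn uniformly
#' from the configured ranges and candidate positions are accepted only if
#' they lie in the right region and at least `d_min` from every element
#' placed so far. Region membership is decided by a point-in-polygon test
#' against the shape outline.
#'
#' `d_min` defaults to 24 arcmin center-to-center (6 Gabor envelope SDs),
#' which keeps neighbouring ±3 SD envelopes from overlapping visibly.
#'
#' @param sampling a `contour_sampling` (the 45 contour positions).
#' @param shape the rescaled, centered `rf_shape` the sampling came from.
#' @param seed integer seed.
#' @param n_interior_range,n_exterior_range inclusive integer ranges for
#'   the interior / exterior element counts.
#' @param d_min minimum center-to-center distance, px.
#' @param array_side array side (px); positions lie in `[margin,
#'   array_side - margin)` where `margin` keeps the Gabor support inside.
#' @param margin border margin in px (default 3 envelope SDs).
#' @param max_attempts candidate draws per region before failing.
#' @return tibble of class `element_field` with columns `x`, `y`,
#'   `region` (factor: interior / contour / exterior); attributes
#'   `d_min`, `array_side`, `counts`.
#' @export
place_elements <- function(sampling, shape, seed,
                           n_interior_range = c(60, 72),
                           n_exterior_range = c(507, 542),
                           n_interior = NULL, n_exterior = NULL,
                           d_min = arcmin_to_px(24),
                           array_side = 496,
                           margin = 3 * arcmin_to_px(4),
                           max_attempts = 200000) {
  stopifnot(inherits(sampling, "contour_sampling"), inherits(shape, "rf_shape"))
  set.seed(seed)
  n_int <- n_interior %||%
    sample(seq(n_interior_range[1], n_interior_range[2]), 1)
  n_ext <- n_exterior %||%
    sample(seq(n_exterior_range[1], n_exterior_range[2]), 1)

  pos <- cbind(sampling$x, sampling$y)
  region <- rep("contour", nrow(pos))
  poly <- shape$polyline

  fill_region <- function(pos, want, inside) {
    got <- 0L
    attempts <- 0L
    while (got < want) {
      if (attempts > max_attempts) {
        stop("element placement failed: could not fit ", want,
             " elements (d_min too large for the requested counts)")
      }
      m <- min(512L, (want - got) * 8L)
      cand <- cbind(stats::runif(m, margin, array_side - margin),
                    stats::runif(m, margin, array_side - margin))
      inp <- mgcv::in.out(rbind(poly, poly[1, ]), cand)
      cand <- cand[if (inside) inp else !inp, , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        d2 <- (pos[, 1] - cand[i, 1])^2 + (pos[, 2] - cand[i, 2])^2
        if (min(d2) >= d_min^2) {
          pos <- rbind(pos, cand[i, ])
          got <- got + 1L
          if (got == want) break
        }
      }
      attempts <- attempts + m
    }
    pos
  }

  pos <- fill_region(pos, n_int, inside = TRUE)
  region <- c(region, rep("interior", n_int))
  pos <- fill_region(pos, n_ext, inside = FALSE)
  region <- c(region, rep("exterior", n_ext))

  out <- tibble::tibble(
    x = pos[, 1], y = pos[, 2],
    region = factor(region, levels = c("interior", "contour", "exterior"))
  )
  attr(out, "d_min") <- d_min
  attr(out, "array_side") <- array_side
  attr(out, "counts") <- c(interior = n_int, contour = nrow(sampling),
                           exterior = n_ext)
  class(out) <- c("element_field", class(out))
  out
}

#' Mean 5-nearest-neighbour distance per region
#'
#' Local density measure: for every element, the mean Euclidean distance
#' to its five nearest neighbours, neighbours taken over the *full*
#' element set; the per-region value is the mean of this quantity over the
#' elements carrying that region label. Reported in arcmin.
#'
#' @param field an `element_field`.
#' @param px_per_arcmin pixels per arcmin (default from the 496 px = 14
#'   deg viewing geometry).
#' @param k number of neighbours (default 5).
#' @return a one-row tibble of class `density_report`: columns
#'   `interior`, `contour`, `exterior` (mean 5-NN distance, arcmin),
#'   `max_pairwise_diff` (arcmin) and `accepted` (logical, diff <= 1).
#' @export
mean_5nn_density <- function(field, px_per_arcmin = 496 / 840, k = 5) {
  stopifnot(inherits(field, "element_field"))
  counts <- table(field$region)
  if (any(counts < k + 1)) {
    stop("each region needs at least ", k + 1, " elements")
  }
  d <- as.matrix(stats::dist(cbind(field$x, field$y)))
  diag(d) <- Inf
  knn_mean <- apply(d, 1, function(row) mean(sort(row, partial = k)[1:k]))
  per_elem_arcmin <- knn_mean / px_per_arcmin
  means <- tapply(per_elem_arcmin, field$region, mean)
  diffs <- abs(outer(means, means, "-"))
  out <- tibble::tibble(
    interior = unname(means["interior"]),
    contour = unname(means["contour"]),
    exterior = unname(means["exterior"]),
    max_pairwise_diff = max(diffs),
    accepted = max(diffs) <= 1
  )
  class(out) <- c("density_report", class(out))
  out
}

#' Density-homogeneity acceptance rule
#'
#' A stimulus is accepted only if its interior, contour and exterior mean
#' local densities (5-NN distances) differ pairwise by at most
#' `tolerance` arcmin.
#'
#' @param report a `density_report`.
#' @param tolerance maximum allowed pairwise difference, arcmin.
#' @return logical flag.
#' @export
accept_stimulus <- function(report, tolerance = 1) {
  stopifnot(inherits(report, "density_report"))
  report$max_pairwise_diff <= tolerance
}

#' Generate one accepted stimulus field
#'
#' Produces a shape plus element field that satisfies the density
#' criterion, mimicking the study procedure of adjusting the interior and
#' exterior element counts separately for every shape:
#'
#' 1. Shapes are drawn (from seeds derived from `seed`) until one is
#'    geometrically compatible: its 45 contour positions must themselves
#'    respect the hard-core distance `d_min`.
#' 2. Counts start at a uniform draw from the configured ranges. After a
#'    rejected placement, each count is nudged toward the (fixed)
#'    contour density -- fewer elements where the region is locally too
#'    dense, more where too sparse -- clamped to the ranges, and the
#'    region is re-placed with a fresh sub-seed.
#' 3. If a shape fails to reach acceptance within `tries_per_shape`
#'    rounds (its contour density can sit outside what the count ranges
#'    can match), the next candidate shape is tried.
#'
#' @param seed integer seed (all sub-draws derive deterministic
#'   sub-seeds).
#' @param tolerance density criterion, arcmin.
#' @param tries_per_shape placement rounds per candidate shape.
#' @param max_shapes candidate shapes before giving up.
#' @param d_min hard-core distance passed to [place_elements()].
#' @param ... further arguments for [place_elements()].
#' @return list with elements `shape`, `sampling`, `field`, `report`,
#'   `tries` (total placement rounds).
#' @export
generate_stimulus <- function(seed, tolerance = 1, tries_per_shape = 25,
                              max_shapes = 40, d_min = arcmin_to_px(24),
                              ...) {
  tries <- 0L
  for (k in seq_len(max_shapes) - 1L) {
    shape_seed <- (seed + 997L * k) %% .Machine$integer.max
    shape <- rescale_and_center(generate_rf_outline(shape_seed))
    sampling <- sample_contour_points(shape)
    if (min(stats::dist(cbind(sampling$x, sampling$y))) < d_min) next
    n_int <- NULL
    n_ext <- NULL
    for (try in seq_len(tries_per_shape)) {
      tries <- tries + 1L
      sub_seed <- (seed * 1009L + tries) %% .Machine$integer.max
      field <- place_elements(sampling, shape, seed = sub_seed,
                              n_interior = n_int, n_exterior = n_ext,
                              d_min = d_min, ...)
      report <- mean_5nn_density(field)
      if (accept_stimulus(report, tolerance)) {
        return(list(shape = shape, sampling = sampling, field = field,
                    report = report, tries = tries))
      }
      cnt <- attr(field, "counts")
      n_int <- steer_count(cnt["interior"], report$interior,
                           report$contour, c(60, 72))
      n_ext <- steer_count(cnt["exterior"], report$exterior,
                           report$contour, c(507, 542))
    }
  }
  stop("no accepted stimulus after ", max_shapes, " candidate shapes")
}

# nudge a region's element count toward the contour density: a region
# whose mean 5-NN distance is below (above) the contour's is too dense
# (too sparse) and loses (gains) elements, within the allowed range
steer_count <- function(count, region_mean, contour_mean, range,
                        gain = 6) {
  step <- round(gain * (region_mean - contour_mean) *
                  count / contour_mean / 10)
  if (step == 0) step <- sign(region_mean - contour_mean)
  as.integer(max(range[1], min(range[2], count + step)))
}
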