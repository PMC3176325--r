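#' Plot a rendered Gabor array
#'
#' @param object a `gabor_image` matrix.
#' @param ... unused.
#' @return a ggplot raster of the greyscale stimulus.
#' @exportS3Method ggplot2::autoplot
autoplot.gabor_image <- function(object, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object)),
                           x = seq_len(ncol(object)))
  df$grey <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot element positions coloured by region
#'
#' @param object an `element_field` (or `gabor_array`).
#' @param ... unused.
#' @return a ggplot point plot.
#' @exportS3Method ggplot2::autoplot
autoplot.element_field <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, colour = .data$region)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot ROI-averaged grand mean waveforms
#'
#' @param waves tidy waveforms from [roi_average()].
#' @return a ggplot of grand means per condition (negative up, the ERP
#'   convention is left to the reader; here positive is up).
#' @export
plot_roi_waveforms <- function(waves) {
  gm <- waves |>
    dplyr::group_by(.data$condition, .data$contour, .data$context,
                    .data$time_ms) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(gm, ggplot2::aes(.data$time_ms, .data$amplitude,
                                   colour = .data$context,
                                   linetype = .data$contour)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time (ms)", y = expression(amplitude ~ (mu * V)),
                  colour = "context", linetype = "contour") +
    ggplot2::theme_minimal()
}

#' Plot the t map of a cluster permutation result
#'
#' @param object a `cluster_result`.
#' @param ... unused.
#' @return a ggplot channel x time heat map with significant-cluster
#'   points outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  tm <- object$tmap
  df <- tidyr::expand_grid(channel = factor(rownames(tm),
                                            levels = rownames(tm)),
                           time_index = seq_len(ncol(tm)))
  df$t <- as.vector(tm)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_index, .data$channel,
                                        fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "time (samples)", y = NULL) +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$significant, ]
  if (nrow(sig)) {
    pts <- dplyr::bind_rows(sig$members)
    pts$channel <- factor(pts$channel, levels = rownames(tm))
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(.data$time_index, .data$channel),
      inherit.aes = FALSE, size = 0.2
    )
  }
  p
}
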