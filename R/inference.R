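#' Average ERPs over the posterior region of interest
#'
#' Collapses an `erp_set` over the ROI channels (default: the 15
#' posterior electrodes) into tidy per-subject, per-condition waveforms.
#'
#' @param erps an `erp_set`.
#' @param layout a `sensor_layout`.
#' @param roi channel labels to average over.
#' @return tibble: subject, condition, contour, context, time_ms,
#'   amplitude (µV).
#' @export
roi_average <- function(erps, layout, roi = layout$roi15) {
  stopifnot(inherits(erps, "erp_set"))
  ci <- match(roi, erps$channels)
  if (anyNA(ci)) stop("missing ROI channel(s): ",
                      paste(roi[is.na(ci)], collapse = ", "))
  w <- apply(erps$data[, ci, , drop = FALSE], c(1, 3), mean)
  meta <- erps$meta
  purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    tibble::tibble(
      subject = meta$subject[i], condition = meta$condition[i],
      contour = meta$contour[i], context = meta$context[i],
      time_ms = erps$time, amplitude = w[i, ]
    )
  })
}

#' Contour-minus-no-contour difference waves
#'
#' @param waves tidy waveforms from [roi_average()].
#' @return tibble: subject, context, time_ms, amplitude (contour minus
#'   no-contour within subject and context).
#' @export
difference_waves <- function(waves) {
  waves |>
    dplyr::select("subject", "contour", "context", "time_ms", "amplitude") |>
    tidyr::pivot_wider(names_from = "contour", values_from = "amplitude",
                       names_prefix = "c") |>
    dplyr::mutate(amplitude = .data$cTRUE - .data$cFALSE) |>
    dplyr::select("subject", "context", "time_ms", "amplitude")
}

#' Default component analysis windows
#'
#' P1 (60--140 ms) and P2 (180--280 ms) are positive-going, N1
#' (120--220 ms) negative-going.
#'
#' @return tibble: component, lo_ms, hi_ms, polarity (+1 / -1).
#' @export
component_windows <- function() {
  tibble::tibble(
    component = c("P1", "N1", "P2"),
    lo_ms = c(60, 120, 180),
    hi_ms = c(140, 220, 280),
    polarity = c(1, -1, 1)
  )
}

#' Windowed component measures on ROI waveforms
#'
#' Mean amplitude is the time average inside the component window; peak
#' latency is the time of the largest peak inside the window -- the
#' signed extremum matching the component's polarity (minimum for N1),
#' ties broken by the earliest sample.
#'
#' @param waves tidy waveforms from [roi_average()].
#' @param windows window definition, see [component_windows()].
#' @return tibble of class `component_measures`: subject, condition,
#'   contour, context, component, mean_amplitude (µV), peak_latency_ms.
#' @export
component_measures <- function(waves, windows = component_windows()) {
  rng <- range(waves$time_ms)
  if (any(windows$lo_ms < rng[1]) || any(windows$hi_ms > rng[2])) {
    stop("component window outside the epoch time range")
  }
  out <- purrr::pmap_dfr(windows, function(component, lo_ms, hi_ms, polarity) {
    waves |>
      dplyr::filter(.data$time_ms >= lo_ms, .data$time_ms <= hi_ms) |>
      dplyr::group_by(.data$subject, .data$condition, .data$contour,
                      .data$context) |>
      dplyr::summarise(
        component = component,
        mean_amplitude = mean(.data$amplitude),
        peak_latency_ms =
          .data$time_ms[which.max(polarity * .data$amplitude)],
        .groups = "drop"
      )
  })
  out <- out[, c("subject", "condition", "contour", "context", "component",
                 "mean_amplitude", "peak_latency_ms")]
  class(out) <- c("component_measures", class(out))
  out
}

#' Component measures with the full / equalized trial-set convention
#'
#' Mean amplitudes are measured on ERPs from the complete artifact-free
#' trial set; peak latencies on ERPs from the count-equalized set (peak
#' estimates are biased by unequal trial counts, time averages are not).
#'
#' @param erps_full `erp_set` from all artifact-free epochs.
#' @param erps_equalized `erp_set` from the equalized epochs.
#' @param layout a `sensor_layout`.
#' @param windows see [component_windows()].
#' @return a `component_measures` tibble (amplitudes from the full set,
#'   latencies from the equalized set).
#' @export
erp_measures <- function(erps_full, erps_equalized, layout,
                         windows = component_windows()) {
  amp <- component_measures(roi_average(erps_full, layout), windows)
  lat <- component_measures(roi_average(erps_equalized, layout), windows)
  key <- c("subject", "condition", "contour", "context", "component")
  out <- dplyr::left_join(amp[, c(key, "mean_amplitude")],
                          lat[, c(key, "peak_latency_ms")], by = key)
  class(out) <- c("component_measures", class(out))
  out
}

#' 2x2 repeated-measures ANOVA with cluster-robust sandwich covariance
#'
#' For every component and measure, fits a linear model with fixed
#' per-subject intercepts plus the contour, context and interaction
#' terms (sum-to-zero coding, so each 1-df term is the Type-III effect),
#' and tests each effect with a Wald F whose covariance is the
#' subject-clustered sandwich (CR1) estimator. Denominator degrees of
#' freedom follow the residual convention `n_obs - n_subjects - 3`
#' (33 for 12 subjects x 4 cells). The classical balanced
#' repeated-measures ANOVA F (each effect against its subject-by-effect
#' interaction, df 1 and n-1) is reported alongside as a cross-check.
#'
#' @param measures a `component_measures` tibble (balanced: every
#'   subject must have all four cells).
#' @return tibble of class `erp_anova`: component, measure, term, F, p,
#'   df1, df2, F_classical, p_classical, estimator.
#' @export
rm_anova_sandwich <- function(measures) {
  stopifnot(inherits(measures, "component_measures"))
  counts <- table(measures$subject, measures$condition, measures$component)
  if (any(counts != 1)) stop("unbalanced table: every subject needs one row per condition and component")
  long <- tidyr::pivot_longer(measures,
                              cols = c("mean_amplitude", "peak_latency_ms"),
                              names_to = "measure", values_to = "value")
  long$measure <- ifelse(long$measure == "mean_amplitude",
                         "mean amplitude", "peak latency")
  grid <- dplyr::distinct(long[, c("component", "measure")])
  out <- purrr::pmap_dfr(grid, function(component, measure) {
    d <- long[long$component == component & long$measure == measure, ]
    d$subject_f <- factor(d$subject)
    d$contour_f <- factor(d$contour, levels = c(FALSE, TRUE))
    d$context_f <- factor(d$context, levels = c("iso", "random"))
    ctr <- list(contour_f = "contr.sum", context_f = "contr.sum")
    fit <- stats::lm(value ~ subject_f + contour_f * context_f, data = d,
                     contrasts = ctr)
    V <- sandwich::vcovCL(fit, cluster = d$subject_f, type = "HC1")
    b <- stats::coef(fit)
    n_sub <- nlevels(d$subject_f)
    df2 <- nrow(d) - n_sub - 3
    terms_map <- c(contour = "contour_f1", context = "context_f1",
                   interaction = "contour_f1:context_f1")
    classical <- classical_rm_anova(d)
    purrr::imap_dfr(terms_map, function(coef_name, term) {
      Fv <- b[coef_name]^2 / V[coef_name, coef_name]
      tibble::tibble(
        component = component, measure = measure, term = term,
        F = unname(Fv), p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
        df1 = 1, df2 = df2,
        F_classical = classical$F[classical$term == term],
        p_classical = classical$p[classical$term == term],
        estimator = "cluster-robust sandwich (CR1)"
      )
    })
  })
  class(out) <- c("erp_anova", class(out))
  out
}

# classical balanced 2x2 within-subject ANOVA via aov error strata
classical_rm_anova <- function(d) {
  fit <- stats::aov(value ~ contour_f * context_f +
                      Error(subject_f / (contour_f * context_f)), data = d,
                    contrasts = list(contour_f = "contr.sum",
                                     context_f = "contr.sum"))
  sm <- summary(fit)
  grab <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  vals <- rbind(
    grab("Error: subject_f:contour_f", "contour_f"),
    grab("Error: subject_f:context_f", "context_f"),
    grab("Error: subject_f:contour_f:context_f", "contour_f:context_f")
  )
  tibble::tibble(term = c("contour", "context", "interaction"),
                 F = vals[, "F"], p = vals[, "p"])
}
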