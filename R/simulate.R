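#' ERP component template
#'
#' Ground-truth description of the three early visual components as
#' Gaussian bumps in time with a posterior-peaked spatial topography.
#' Baseline latencies and amplitudes describe the no-contour /
#' iso-oriented cell; condition effects are added by an [effect_spec()].
#'
#' @param components tibble with columns `component`, `latency_ms`,
#'   `width_ms` (Gaussian temporal SD), `amplitude_uv` (signed peak).
#' @return tibble of class `erp_template`.
#' @export
erp_template <- function(components = tibble::tibble(
                           component    = c("P1", "N1", "P2"),
                           latency_ms   = c(100, 149, 220),
                           width_ms     = c(12, 18, 25),
                           amplitude_uv = c(3, -6, 4))) {
  stopifnot(all(c("component", "latency_ms", "width_ms", "amplitude_uv")
                %in% names(components)))
  class(components) <- c("erp_template", class(components))
  components
}

#' Condition effects for the 2x2 design
#'
#' Additive amplitude deltas (µV) and latency shifts (ms) per component
#' for the three design terms, coded so that a cell with contour `c`
#' (0/1) and context `x` (0 = iso, 1 = random) has
#' `delta = c*contour + x*context + c*x*interaction`.
#'
#' The defaults emulate the qualitative pattern reported for this
#' paradigm: the N1 peaks 13 ms later (149 to 162 ms) and grows more
#' negative with an embedded contour, with a larger contour effect under
#' iso-oriented context (negative interaction released under random
#' context); the P1 is larger under random context; the P2 is smaller and
#' 9 ms later (220 to 229 ms) with a contour. These are emulation
#' settings for recovery testing, not claims about any recorded data.
#'
#' @param effects tibble with columns `component`, `term` (contour /
#'   context / interaction), `d_amplitude_uv`, `d_latency_ms`.
#' @return tibble of class `effect_spec`.
#' @export
effect_spec <- function(effects = tibble::tribble(
                          ~component, ~term,         ~d_amplitude_uv, ~d_latency_ms,
                          "P1",       "contour",      0,               0,
                          "P1",       "context",      0.8,             0,
                          "P1",       "interaction",  0,               0,
                          "N1",       "contour",     -2.5,            13,
                          "N1",       "context",      1.0,             0,
                          "N1",       "interaction",  1.5,             0,
                          "P2",       "contour",     -1.5,             9,
                          "P2",       "context",      0,               0,
                          "P2",       "interaction",  0,               0)) {
  class(effects) <- c("effect_spec", class(effects))
  effects
}

#' Ground-truth component parameters per design cell
#'
#' @param template an [erp_template()].
#' @param effects an [effect_spec()].
#' @return tibble: component, contour (logical), context, `latency_ms`,
#'   `amplitude_uv` for each of the four cells.
#' @export
cell_parameters <- function(template = erp_template(), effects = effect_spec()) {
  cells <- tidyr::expand_grid(contour = c(FALSE, TRUE),
                              context = c("iso", "random"))
  purrr::pmap_dfr(cells, function(contour, context) {
    out <- tibble::as_tibble(template)[, c("component", "latency_ms",
                                           "width_ms", "amplitude_uv")]
    for (i in seq_len(nrow(out))) {
      e <- effects[effects$component == out$component[i], ]
      cc <- as.numeric(contour)
      xx <- as.numeric(context == "random")
      w <- c(contour = cc, context = xx, interaction = cc * xx)
      d_amp <- sum(w[e$term] * e$d_amplitude_uv)
      d_lat <- sum(w[e$term] * e$d_latency_ms)
      out$amplitude_uv[i] <- out$amplitude_uv[i] + d_amp
      out$latency_ms[i] <- out$latency_ms[i] + d_lat
    }
    dplyr::mutate(out, contour = contour, context = context, .before = 1)
  })
}

#' Posterior component topography over a sensor layout
#'
#' Gaussian spatial profile on the 2-D projected positions, centred over
#' the occipito-parietal midline so its maximum falls on the 15-channel
#' posterior ROI. Weights are normalized to max 1; auxiliary channels
#' (mastoids, EOG) get weight 0.
#'
#' @param layout a `sensor_layout`.
#' @param center topography centre in layout coordinates.
#' @param spread Gaussian SD in layout coordinates.
#' @return named numeric vector over all layout channels.
#' @export
component_topography <- function(layout, center = c(0, -0.75), spread = 0.45) {
  ch <- layout$channels
  w <- exp(-((ch$x - center[1])^2 + (ch$y - center[2])^2) / (2 * spread^2))
  w[ch$type != "scalp"] <- 0
  w <- w / max(w)
  stats::setNames(w, ch$label)
}

blink_topography <- function(layout) {
  ch <- layout$channels
  w <- exp(-((ch$x - 0)^2 + (ch$y - 0.95)^2) / (2 * 0.35^2))
  w[ch$type %in% c("mastoid")] <- 0
  w[ch$label == "VEOG"] <- 1.6      # ocular channel sees the blink largest
  w[ch$label == "HEOG"] <- 0.3
  stats::setNames(w, ch$label)
}

#' Epoched EEG container
#'
#' @param data numeric array `n_epochs x n_channels x n_time`, µV.
#' @param channels channel labels.
#' @param time time axis in ms relative to stimulus onset.
#' @param fs sampling rate, Hz.
#' @param meta tibble with one row per epoch (subject, contour, context,
#'   condition, artifact ground truth, ...).
#' @param ground_truth optional tibble of simulation ground truth.
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, channels, time, fs, meta, ground_truth = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == nrow(meta),
            dim(data)[2] == length(channels), dim(data)[3] == length(time))
  structure(list(data = data, channels = channels, time = time, fs = fs,
                 meta = meta, ground_truth = ground_truth),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " epochs x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples (",
      min(x$time), "..", max(x$time), " ms @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

# pink (1/f) noise, one channel x time matrix per call; columns are time
pink_noise <- function(n_ch, n_t) {
  white <- matrix(stats::rnorm(n_ch * n_t), n_ch, n_t)
  spec <- stats::mvfft(t(white))
  f <- seq_len(n_t) - 1
  f <- pmin(f, n_t - f)                       # two-sided frequency index
  g <- ifelse(f == 0, 0, 1 / sqrt(f))
  x <- Re(stats::mvfft(spec * g, inverse = TRUE)) / n_t
  t(x)
}

# spatially smooth scalp rows by one-step graph diffusion, then rescale
# the whole matrix to the requested RMS
spatial_noise <- function(layout, n_t, rms) {
  ch <- layout$channels
  n_ch <- nrow(ch)
  x <- pink_noise(n_ch, n_t)
  scalp <- which(ch$type == "scalp")
  A <- layout$adjacency
  P <- A / rowSums(A)
  xs <- x[scalp, , drop = FALSE]
  # one diffusion step, I + P/2: spectrum in [1/2, 3/2], so the spatial
  # covariance stays full rank (whitening-friendly)
  x[scalp, ] <- xs + 0.5 * (P %*% xs)
  x * (rms / stats::sd(x))
}

gauss_bump <- function(time, latency, width) {
  exp(-(time - latency)^2 / (2 * width^2))
}

#' Simulate epoched EEG for one subject
#'
#' Each epoch is the sum of the three component bumps (Gaussian in time,
#' posterior topography in space, cell-specific amplitude/latency), plus
#' spatially correlated 1/f noise, optional blink transients, and
#' optional gross-amplitude artifact epochs whose ground truth is stored
#' in the epoch metadata.
#'
#' @param layout a `sensor_layout`.
#' @param template an [erp_template()].
#' @param effects an [effect_spec()].
#' @param n_trials epochs per design cell.
#' @param noise_rms noise RMS in µV (0 gives noiseless epochs).
#' @param artifact_prob probability an epoch receives a ±150 µV spike.
#' @param blink_prob probability an epoch receives a blink transient.
#' @param seed integer seed.
#' @param subject subject id stored in the metadata.
#' @param time time axis, ms.
#' @param fs sampling rate, Hz.
#' @return an [eeg_epochs()] with ground-truth cell parameters attached.
#' @export
simulate_subject <- function(layout, template = erp_template(),
                             effects = effect_spec(), n_trials = 20,
                             noise_rms = 8, artifact_prob = 0,
                             blink_prob = 0, seed = 1, subject = 1,
                             time = -200:599, fs = 1000) {
  stopifnot(n_trials >= 1, noise_rms >= 0)
  set.seed(seed)
  pars <- cell_parameters(template, effects)
  topo <- component_topography(layout)
  btopo <- blink_topography(layout)
  labels <- layout$channels$label
  n_ch <- length(labels); n_t <- length(time)
  cells <- tidyr::expand_grid(contour = c(FALSE, TRUE),
                              context = c("iso", "random"))
  n_epochs <- nrow(cells) * n_trials
  data <- array(0, c(n_epochs, n_ch, n_t))
  meta <- list()
  e <- 0L
  for (ci in seq_len(nrow(cells))) {
    p <- pars[pars$contour == cells$contour[ci] &
                pars$context == cells$context[ci], ]
    erp <- matrix(0, n_ch, n_t)
    for (k in seq_len(nrow(p))) {
      erp <- erp + p$amplitude_uv[k] * topo %o%
        gauss_bump(time, p$latency_ms[k], p$width_ms[k])
    }
    for (tr in seq_len(n_trials)) {
      e <- e + 1L
      ep <- erp
      if (noise_rms > 0) ep <- ep + spatial_noise(layout, n_t, noise_rms)
      blink <- stats::runif(1) < blink_prob
      if (blink) {
        onset <- sample(time[time < max(time) - 300], 1)
        wave <- pmax(0, sin((time - onset) / 300 * pi)) *
          (time >= onset & time <= onset + 300)
        ep <- ep + 120 * btopo %o% wave
      }
      artifact <- stats::runif(1) < artifact_prob
      if (artifact) {
        ch <- sample(which(layout$channels$type == "scalp"), 1)
        at <- sample(seq_len(n_t - 20), 1)
        ep[ch, at:(at + 19)] <- ep[ch, at:(at + 19)] +
          sample(c(-150, 150), 1)
      }
      data[e, , ] <- ep
      meta[[e]] <- tibble::tibble(
        subject = subject, contour = cells$contour[ci],
        context = cells$context[ci],
        condition = paste0(ifelse(cells$contour[ci], "contour", "no-contour"),
                           "/", cells$context[ci]),
        trial = tr, artifact_truth = artifact, blink_truth = blink
      )
    }
  }
  eeg_epochs(data, labels, time, fs, dplyr::bind_rows(meta),
             ground_truth = pars)
}

#' Simulate a multi-subject cohort
#'
#' Per-subject templates are jittered by between-subject SDs on component
#' amplitudes and latencies; every subject contributes balanced cells.
#'
#' @param layout a `sensor_layout`.
#' @param n_subjects number of subjects (default 12).
#' @param n_trials trials per cell per subject.
#' @param between_sd named vector: `amp` (µV) and `lat` (ms) SDs of the
#'   subject-level jitter on every component.
#' @param seed integer seed.
#' @inheritParams simulate_subject
#' @return an [eeg_epochs()] covering all subjects; `ground_truth` holds
#'   the per-subject cell parameters.
#' @export
simulate_cohort <- function(layout, n_subjects = 12, n_trials = 20,
                            template = erp_template(),
                            effects = effect_spec(),
                            between_sd = c(amp = 0.5, lat = 4),
                            noise_rms = 8, artifact_prob = 0,
                            blink_prob = 0, seed = 1, time = -200:599,
                            fs = 1000) {
  stopifnot(n_subjects >= 2)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  # all subject-level template jitter is drawn up front, so the cohort
  # ground truth depends on `seed` alone (not on noise settings)
  n_comp <- nrow(template)
  amp_jit <- matrix(stats::rnorm(n_subjects * n_comp, 0, between_sd["amp"]),
                    n_subjects, n_comp)
  lat_jit <- matrix(stats::rnorm(n_subjects * n_comp, 0, between_sd["lat"]),
                    n_subjects, n_comp)
  pieces <- vector("list", n_subjects)
  truths <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    tpl <- tibble::as_tibble(template)
    tpl$amplitude_uv <- tpl$amplitude_uv + amp_jit[s, ]
    tpl$latency_ms <- tpl$latency_ms + lat_jit[s, ]
    pieces[[s]] <- simulate_subject(
      layout, erp_template(tpl), effects, n_trials = n_trials,
      noise_rms = noise_rms, artifact_prob = artifact_prob,
      blink_prob = blink_prob, seed = sub_seeds[s], subject = s,
      time = time, fs = fs
    )
    truths[[s]] <- dplyr::mutate(pieces[[s]]$ground_truth, subject = s,
                                 .before = 1)
  }
  data <- do.call(abind1, lapply(pieces, function(p) p$data))
  meta <- dplyr::bind_rows(lapply(pieces, function(p) p$meta))
  eeg_epochs(data, pieces[[1]]$channels, time, fs, meta,
             ground_truth = dplyr::bind_rows(truths))
}

# bind 3-d arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Continuous EEG container
#'
#' @param data numeric matrix channels x samples, µV.
#' @param channels channel labels.
#' @param fs sampling rate, Hz.
#' @param events tibble of stimulus events (`onset_ms`, condition
#'   columns).
#' @param blink_truth optional tibble of injected blink onsets.
#' @return object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, channels, fs, events = NULL,
                           blink_truth = NULL) {
  stopifnot(nrow(data) == length(channels))
  structure(list(data = data, channels = channels, fs = fs,
                 events = events, blink_truth = blink_truth),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat("<eeg_continuous> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 1),
      " s), ", if (is.null(x$events)) 0 else nrow(x$events),
      " events\n", sep = "")
  invisible(x)
}

#' Simulate continuous EEG for a trial sequence
#'
#' Renders stimulus-locked component responses at every event onset on
#' top of spatially correlated 1/f noise, with eye blinks injected as a
#' Poisson process (dipolar frontal topography, 300 ms waveform, written
#' to VEOG as well). This is the input expected by the preprocessing
#' chain, which removes the blinks via SOBI before epoching.
#'
#' @param layout a `sensor_layout`.
#' @param events tibble with `onset_ms`, `contour`, `context` columns
#'   (e.g. the analysis trials of [build_session()]).
#' @param template,effects ground-truth ERP description.
#' @param noise_rms noise RMS, µV.
#' @param blink_rate blinks per minute.
#' @param blink_amp peak blink amplitude at the ocular channel, µV.
#' @param pad_ms flat padding before the first / after the last event.
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @return an [eeg_continuous()].
#' @export
simulate_continuous <- function(layout, events, template = erp_template(),
                                effects = effect_spec(), noise_rms = 8,
                                blink_rate = 4, blink_amp = 150,
                                pad_ms = 500, seed = 1, fs = 1000) {
  set.seed(seed)
  pars <- cell_parameters(template, effects)
  topo <- component_topography(layout)
  btopo <- blink_topography(layout)
  labels <- layout$channels$label
  events$onset_ms <- events$onset_ms - min(events$onset_ms) + pad_ms
  dur <- max(events$onset_ms) + 1000 + pad_ms
  n_t <- ceiling(dur * fs / 1000)
  n_ch <- length(labels)
  data <- matrix(0, n_ch, n_t)
  if (noise_rms > 0) {
    # generate noise in chunks to bound the FFT size
    chunk <- 20000L
    at <- 1L
    while (at <= n_t) {
      idx <- at:min(n_t, at + chunk - 1L)
      data[, idx] <- spatial_noise(layout, length(idx), noise_rms)
      at <- at + chunk
    }
  }
  t_resp <- 0:599
  for (i in seq_len(nrow(events))) {
    p <- pars[pars$contour == events$contour[i] &
                pars$context == events$context[i], ]
    resp <- matrix(0, n_ch, length(t_resp))
    for (k in seq_len(nrow(p))) {
      resp <- resp + p$amplitude_uv[k] * topo %o%
        gauss_bump(t_resp, p$latency_ms[k], p$width_ms[k])
    }
    s0 <- round(events$onset_ms[i] * fs / 1000) + 1L
    idx <- s0:min(n_t, s0 + length(t_resp) - 1L)
    data[, idx] <- data[, idx] + resp[, seq_along(idx)]
  }
  n_blinks <- stats::rpois(1, blink_rate * dur / 60000)
  blink_on <- sort(stats::runif(n_blinks, 0, dur - 400))
  bw_ms <- 0:299
  bwave <- sin(bw_ms / 300 * pi)
  for (b in blink_on) {
    s0 <- round(b * fs / 1000) + 1L
    idx <- s0:min(n_t, s0 + length(bwave) - 1L)
    data[, idx] <- data[, idx] +
      (blink_amp / max(btopo)) * btopo %o% bwave[seq_along(idx)]
  }
  eeg_continuous(data, labels, fs, events = events,
                 blink_truth = tibble::tibble(onset_ms = blink_on))
}
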