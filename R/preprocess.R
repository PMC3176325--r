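#' Re-reference to the average of the two mastoids
#'
#' Subtracts (M1 + M2)/2 from every channel at every sample. Idempotent:
#' once the mastoid average is zero, applying the operation again changes
#' nothing.
#'
#' @param x an `eeg_continuous` or `eeg_epochs` containing M1 and M2.
#' @return the re-referenced object.
#' @export
rereference_mastoids <- function(x) {
  if (inherits(x, "eeg_continuous")) {
    m <- match(c("M1", "M2"), x$channels)
    if (anyNA(m)) stop("mastoid channels M1/M2 missing")
    ref <- colMeans(x$data[m, , drop = FALSE])
    x$data <- sweep(x$data, 2, ref)
    x
  } else if (inherits(x, "eeg_epochs")) {
    m <- match(c("M1", "M2"), x$channels)
    if (anyNA(m)) stop("mastoid channels M1/M2 missing")
    ref <- (x$data[, m[1], ] + x$data[, m[2], ]) / 2   # epochs x time
    for (ch in seq_along(x$channels)) {
      x$data[, ch, ] <- x$data[, ch, ] - ref
    }
    x
  } else {
    stop("unsupported input")
  }
}

#' Zero-phase lowpass filter
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and a -3 dB point at the
#' cutoff.
#'
#' @param x an `eeg_continuous`.
#' @param cutoff_hz cutoff frequency (default 30 Hz).
#' @param order filter order of the one-pass prototype.
#' @return the filtered object.
#' @export
lowpass_30 <- function(x, cutoff_hz = 30, order = 4) {
  stopifnot(inherits(x, "eeg_continuous"))
  if (x$fs <= 2 * cutoff_hz) stop("sampling rate too low for this cutoff")
  bf <- signal::butter(order, cutoff_hz / (x$fs / 2), type = "low")
  for (i in seq_len(nrow(x$data))) {
    x$data[i, ] <- signal::filtfilt(bf, x$data[i, ])
  }
  x
}

#' Epoch continuous data and apply baseline correction
#'
#' Cuts an 800 ms window starting 200 ms before each event onset and
#' subtracts, per epoch and channel, the mean over the 200 ms
#' pre-stimulus interval. Events too close to the recording edges are
#' skipped and counted in the `skipped` attribute.
#'
#' @param x an `eeg_continuous`.
#' @param events tibble with `onset_ms` (defaults to `x$events`); all
#'   other columns are carried into the epoch metadata.
#' @param pre_ms,post_ms window extent around onset (pre is positive).
#' @return an [eeg_epochs()] with time axis `-pre_ms .. post_ms - 1` ms.
#' @export
epoch_and_baseline <- function(x, events = NULL, pre_ms = 200,
                               post_ms = 600) {
  stopifnot(inherits(x, "eeg_continuous"))
  events <- events %||% x$events
  if (is.null(events)) stop("no events supplied")
  spms <- x$fs / 1000
  n_t <- round((pre_ms + post_ms) * spms)
  time <- seq(-pre_ms, by = 1000 / x$fs, length.out = n_t)
  onset_s <- round(events$onset_ms * spms) + 1L
  lo <- onset_s - round(pre_ms * spms)
  hi <- lo + n_t - 1L
  ok <- lo >= 1 & hi <= ncol(x$data)
  n_skip <- sum(!ok)
  events <- events[ok, , drop = FALSE]
  lo <- lo[ok]
  n_bl <- round(pre_ms * spms)
  data <- array(0, c(nrow(events), nrow(x$data), n_t))
  for (e in seq_len(nrow(events))) {
    seg <- x$data[, lo[e]:(lo[e] + n_t - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg[, seq_len(n_bl), drop = FALSE])
    data[e, , ] <- seg
  }
  out <- eeg_epochs(data, x$channels, time, x$fs,
                    tibble::as_tibble(events))
  attr(out, "skipped") <- n_skip
  out
}

#' Reject gross-amplitude artifact epochs
#'
#' Drops every epoch in which any scalp channel strictly exceeds
#' ±`threshold_uv` at any sample (an epoch peaking at exactly the
#' threshold is retained). Ocular and mastoid channels are not
#' consulted, since blink activity is handled upstream by SOBI.
#'
#' @param epochs an `eeg_epochs`.
#' @param threshold_uv rejection threshold, µV.
#' @param channels channel labels to scan (default: all but M1, M2,
#'   VEOG, HEOG).
#' @return the retained epochs; attribute `rejection_log` is a one-row
#'   tibble (n_in, n_rejected, n_out) and the dropped epoch indices are
#'   in attribute `rejected`.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100, channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  channels <- channels %||%
    setdiff(epochs$channels, c("M1", "M2", "VEOG", "HEOG"))
  ci <- match(channels, epochs$channels)
  n <- dim(epochs$data)[1]
  peak <- apply(abs(epochs$data[, ci, , drop = FALSE]), 1, max)
  bad <- which(peak > threshold_uv)
  if (length(bad) == n) stop("all epochs exceeded the rejection threshold")
  keep <- setdiff(seq_len(n), bad)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$meta <- epochs$meta[keep, , drop = FALSE]
  attr(out, "rejected") <- bad
  attr(out, "rejection_log") <- tibble::tibble(
    n_in = n, n_rejected = length(bad), n_out = length(keep)
  )
  out
}

#' Equalize epoch counts across cells
#'
#' Randomly removes epochs so every subject x condition cell keeps the
#' global minimum count (the convention required by peak-latency
#' analyses, where unequal trial counts bias peak estimates).
#'
#' @param epochs an `eeg_epochs` whose metadata has `subject` and
#'   `condition` columns.
#' @param seed integer seed for the random removal.
#' @return the trimmed `eeg_epochs`.
#' @export
equalize_counts <- function(epochs, seed = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  set.seed(seed)
  cell <- interaction(epochs$meta$subject, epochs$meta$condition, drop = TRUE)
  counts <- table(cell)
  if (any(counts == 0)) stop("empty subject x condition cell")
  m <- min(counts)
  keep <- unlist(lapply(split(seq_along(cell), cell), function(idx) {
    if (length(idx) > m) sort(sample(idx, m)) else idx
  }), use.names = FALSE)
  keep <- sort(keep)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$meta <- epochs$meta[keep, , drop = FALSE]
  out
}

#' Condition-specific ERP container
#'
#' @param data array `n_cells x n_channels x n_time`, µV.
#' @param channels,time,fs axes, as in [eeg_epochs()].
#' @param meta tibble with one row per cell (subject, condition,
#'   contour, context, n_epochs).
#' @return object of class `erp_set`.
#' @export
erp_set <- function(data, channels, time, fs, meta) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == nrow(meta))
  structure(list(data = data, channels = channels, time = time, fs = fs,
                 meta = meta), class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat("<erp_set> ", nrow(x$meta), " subject x condition waveforms (",
      dim(x$data)[2], " channels x ", dim(x$data)[3], " samples)\n",
      sep = "")
  invisible(x)
}

#' Robust (bisquare IRLS) trial averaging
#'
#' Iteratively re-weighted mean across epochs, per channel and sample:
#' residuals from the current mean are scaled by a per-channel MAD-based
#' robust scale, converted to Tukey bisquare weights (tuning constant
#' 4.685), and the weighted mean is re-computed, for at most `max_iter`
#' iterations. Outlying samples are down-weighted smoothly instead of
#' discarding whole trials.
#'
#' @param epochs an `eeg_epochs` with `subject` and `condition` metadata.
#' @param max_iter IRLS iteration cap.
#' @param tuning bisquare tuning constant (in robust-scale units).
#' @return an [erp_set()] with one waveform per subject x condition;
#'   `meta$n_epochs` records the contributing trial counts.
#' @export
robust_average <- function(epochs, max_iter = 10, tuning = 4.685) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- epochs$meta
  cells <- dplyr::distinct(meta[, intersect(c("subject", "contour",
                                              "context", "condition"),
                                            names(meta))])
  cells <- cells[order(cells$subject, cells$condition), ]
  n_ch <- dim(epochs$data)[2]; n_t <- dim(epochs$data)[3]
  out <- array(0, c(nrow(cells), n_ch, n_t))
  n_ep <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- meta$subject == cells$subject[i] &
      meta$condition == cells$condition[i]
    X <- epochs$data[sel, , , drop = FALSE]
    n_ep[i] <- dim(X)[1]
    if (dim(X)[1] < 2) stop("robust averaging needs >= 2 epochs per cell")
    out[i, , ] <- robust_mean_trials(X, max_iter, tuning)
  }
  cells$n_epochs <- n_ep
  erp_set(out, epochs$channels, epochs$time, epochs$fs, cells)
}

# X: trials x channels x time; returns channels x time robust mean
robust_mean_trials <- function(X, max_iter = 10, tuning = 4.685) {
  n_tr <- dim(X)[1]; n_ch <- dim(X)[2]; n_t <- dim(X)[3]
  Xm <- matrix(X, n_tr, n_ch * n_t)        # column j: channel, then time
  ch_of_col <- rep(seq_len(n_ch), times = n_t)
  mu <- colMeans(Xm)
  W <- matrix(1, n_tr, n_ch * n_t)
  for (iter in seq_len(max_iter)) {
    R <- Xm - rep(mu, each = n_tr)
    # robust scale per channel, pooled over trials and time
    s <- vapply(seq_len(n_ch), function(ch) {
      stats::median(abs(R[, ch_of_col == ch])) * 1.4826
    }, numeric(1))
    s[s < 1e-12] <- 1e-12
    U <- R / rep(tuning * s[ch_of_col], each = n_tr)
    W <- (1 - U^2)^2
    W[abs(U) >= 1] <- 0
    den <- colSums(W)
    num <- colSums(W * Xm)
    mu_new <- ifelse(den > 0, num / den, mu)
    delta <- max(abs(mu_new - mu))
    mu <- mu_new
    if (delta < 1e-8) break
  }
  out <- matrix(mu, n_ch, n_t)
  attr(out, "weights") <- array(W, c(n_tr, n_ch, n_t))
  out
}

#' Plain (arithmetic) trial averaging
#'
#' Companion to [robust_average()] used for comparisons.
#'
#' @inheritParams robust_average
#' @return an [erp_set()].
#' @export
plain_average <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- epochs$meta
  cells <- dplyr::distinct(meta[, intersect(c("subject", "contour",
                                              "context", "condition"),
                                            names(meta))])
  cells <- cells[order(cells$subject, cells$condition), ]
  out <- array(0, c(nrow(cells), dim(epochs$data)[2], dim(epochs$data)[3]))
  n_ep <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- meta$subject == cells$subject[i] &
      meta$condition == cells$condition[i]
    out[i, , ] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    n_ep[i] <- sum(sel)
  }
  cells$n_epochs <- n_ep
  erp_set(out, epochs$channels, epochs$time, epochs$fs, cells)
}

#' Run the full offline preprocessing chain on continuous data
#'
#' Fixed order: mastoid re-reference, 30 Hz zero-phase lowpass, SOBI
#' blink removal, epoching with baseline correction, ±100 µV artifact
#' rejection, robust averaging -- plus an equalized-count branch used by
#' peak-latency analyses.
#'
#' @param x an `eeg_continuous` with events carrying `contour`,
#'   `context` and `condition` columns (plus `subject`).
#' @param sobi logical; fit and apply SOBI blink removal (skip for data
#'   known to be blink-free, e.g. noiseless validation runs).
#' @param equalize_seed seed for the trial-count equalization.
#' @param reject_threshold rejection threshold, µV.
#' @return list: `erps_full` (robust averages of all artifact-free
#'   epochs), `erps_equalized` (same after count equalization),
#'   `epochs` (retained epochs), `log` (per-stage counts).
#' @export
preprocess_pipeline <- function(x, sobi = TRUE, equalize_seed = 1,
                                reject_threshold = 100) {
  stopifnot(inherits(x, "eeg_continuous"))
  x <- rereference_mastoids(x)
  x <- lowpass_30(x)
  if (sobi) {
    model <- sobi_fit(x)
    x <- remove_blinks(x, model)
  }
  epochs <- epoch_and_baseline(x)
  kept <- reject_artifacts(epochs, reject_threshold)
  erps_full <- robust_average(kept)
  eq <- equalize_counts(kept, seed = equalize_seed)
  erps_eq <- robust_average(eq)
  log <- tibble::tibble(
    stage = c("epoched", "rejected", "retained", "equalized"),
    n = c(dim(epochs$data)[1],
          attr(kept, "rejection_log")$n_rejected,
          dim(kept$data)[1], dim(eq$data)[1])
  )
  list(erps_full = erps_full, erps_equalized = erps_eq, epochs = kept,
       log = log)
}
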