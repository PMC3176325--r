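#' Sample inter-stimulus intervals
#'
#' ISIs are i.i.d. uniform between 800 and 1200 ms.
#'
#' @param seed integer seed.
#' @param n number of intervals.
#' @param range ISI range in ms.
#' @return numeric vector of ISIs (ms).
#' @export
sample_isi <- function(seed, n, range = c(800, 1200)) {
  stopifnot(n >= 1)
  set.seed(seed)
  stats::runif(n, range[1], range[2])
}

# number of no-contour trials preceding each contour trial: k on {1..5}
# with geometrically tilted weights q^k. q = 0.64 gives E[k] ~ 2.18 =
# 0.61/0.28, so the expected stimulus-trial fractions match the design
# frequencies (contour 0.28, no-contour 0.61) once 11% catch trials are
# mixed in.
sample_motif_k <- function(n, q = 0.64) {
  w <- q^(1:5)
  sample(1:5, n, replace = TRUE, prob = w / sum(w))
}

#' Build a session trial sequence
#'
#' Builds `n_blocks` blocks (two with iso-oriented and two with
#' randomly-oriented context, order counterbalanced across participants)
#' of pseudo-randomized trials honouring the ordering constraints:
#' every contour trial is preceded by 1--5 no-contour trials sharing its
#' position set, and followed by a no-contour trial with a fresh position
#' set; the first no-contour trial after a contour trial is flagged
#' `exclude_from_analysis`; catch trials (circle-detection attention
#' checks) are randomly intermixed at an 0.11 rate and never counted in
#' the ordering patterns. Stimulus-trial frequencies converge to
#' contour 0.28 / no-contour 0.61 / catch 0.11.
#'
#' Sequences are built from motifs `[no-contour x k, contour]` where all
#' k + 1 trials share one position set and k is drawn on {1..5} with mean
#' 0.61/0.28 (see Details in the package vignette).
#'
#' @param seed integer seed.
#' @param n_blocks number of blocks (default 4: 2 iso + 2 random).
#' @param trials_per_block approximate trials per block (default 270,
#'   about five minutes at a 106 ms stimulus plus a 1 s mean ISI).
#' @param participant participant index used to counterbalance block
#'   order (Latin-square style rotation over the distinct orders of two
#'   iso and two random blocks).
#' @param catch_rate target catch-trial fraction.
#' @param stim_duration_ms stimulus duration (106 ms: 9 frames at 85 Hz).
#' @return a tibble of class `trial_sequence`: columns `index`, `block`,
#'   `context`, `condition` (contour / no-contour / catch), `catch`,
#'   `position_set`, `orientation_seed`, `onset_ms`, `duration_ms`,
#'   `isi_ms`, `exclude_from_analysis`.
#' @export
build_session <- function(seed, n_blocks = 4, trials_per_block = 270,
                          participant = 1, catch_rate = 0.11,
                          stim_duration_ms = 106) {
  if (trials_per_block < 50) stop("`trials_per_block` must be at least 50")
  set.seed(seed)
  orders <- list(c("iso", "iso", "random", "random"),
                 c("iso", "random", "iso", "random"),
                 c("iso", "random", "random", "iso"),
                 c("random", "iso", "iso", "random"),
                 c("random", "iso", "random", "iso"),
                 c("random", "random", "iso", "iso"))
  ctx <- rep(orders[[(participant - 1) %% length(orders) + 1]],
             length.out = n_blocks)

  position_set <- 0L
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    n_stim_target <- ceiling(trials_per_block * (1 - catch_rate))
    cond <- character(0)
    pset <- integer(0)
    excl <- logical(0)
    first_motif <- TRUE
    while (length(cond) < n_stim_target) {
      k <- sample_motif_k(1)
      position_set <- position_set + 1L
      cond <- c(cond, rep("no-contour", k), "contour")
      pset <- c(pset, rep(position_set, k + 1L))
      excl <- c(excl, !first_motif, rep(FALSE, k))
      first_motif <- FALSE
    }
    if (cond[length(cond)] == "contour") {
      # a contour trial is always followed by a no-contour trial with
      # fresh positions; close the block with one (excluded from analysis)
      position_set <- position_set + 1L
      cond <- c(cond, "no-contour")
      pset <- c(pset, position_set)
      excl <- c(excl, TRUE)
    }
    n_stim <- length(cond)
    n_catch <- round(n_stim * catch_rate / (1 - catch_rate))
    slots <- sort(sample(seq_len(n_stim + n_catch), n_catch))
    cond_full <- character(n_stim + n_catch)
    cond_full[slots] <- "catch"
    cond_full[-slots] <- cond
    pset_full <- integer(n_stim + n_catch)
    pset_full[-slots] <- pset
    excl_full <- logical(n_stim + n_catch)
    excl_full[-slots] <- excl
    excl_full[slots] <- TRUE
    # catch trials reuse the positions current at their slot
    pset_full[slots] <- vapply(slots, function(s) {
      prev <- pset_full[seq_len(s - 1)]
      prev <- prev[prev > 0L]
      if (length(prev)) prev[length(prev)] else pset_full[pset_full > 0L][1]
    }, integer(1))
    blocks[[b]] <- tibble::tibble(
      block = b, context = ctx[b], condition = cond_full,
      catch = cond_full == "catch", position_set = pset_full,
      exclude_from_analysis = excl_full
    )
  }
  out <- dplyr::bind_rows(blocks)
  n <- nrow(out)
  out$index <- seq_len(n)
  out$orientation_seed <- (seed + 7919L * out$index) %% .Machine$integer.max
  out$isi_ms <- sample_isi(seed + 1L, n)
  out$duration_ms <- stim_duration_ms
  out$onset_ms <- cumsum(c(0, (out$duration_ms + out$isi_ms)[-n]))
  out <- out[, c("index", "block", "context", "condition", "catch",
                 "position_set", "orientation_seed", "onset_ms",
                 "duration_ms", "isi_ms", "exclude_from_analysis")]
  class(out) <- c("trial_sequence", class(out))
  out
}

#' Tabulate condition frequencies of a session
#'
#' @param trials a `trial_sequence`.
#' @return a tibble with columns `condition`, `n`, `fraction`.
#' @export
condition_frequencies <- function(trials) {
  stopifnot(inherits(trials, "trial_sequence"))
  dplyr::count(tibble::as_tibble(trials), .data$condition, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}
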