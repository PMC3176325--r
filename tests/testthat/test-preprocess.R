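layout_p <- make_layout()

make_cont <- function(data, channels, fs = 1000, events = NULL) {
  eeg_continuous(data, channels, fs, events = events)
}

test_that("mastoid re-referencing removes the common mode and is idempotent", {
  set.seed(1)
  chans <- c("Oz", "Pz", "M1", "M2", "VEOG")
  X <- matrix(rnorm(5 * 500), 5, 500)
  cont <- make_cont(X, chans)
  out <- rereference_mastoids(cont)
  m <- colMeans(out$data[3:4, ])
  expect_lt(max(abs(m)), 1e-12)
  # channel differences unchanged
  expect_equal(out$data[1, ] - out$data[2, ], X[1, ] - X[2, ])
  # idempotent
  out2 <- rereference_mastoids(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(rereference_mastoids(make_cont(X[1:2, ], chans[1:2])),
               "mastoid")
})

test_that("the 30 Hz lowpass passes 5 Hz, attenuates 100 Hz, and is zero phase", {
  t <- seq(0, 2, by = 1e-3)[-1]
  s5 <- sin(2 * pi * 5 * t)
  s100 <- sin(2 * pi * 100 * t)
  X <- rbind(s5, s100)
  cont <- make_cont(X, c("a", "b"))
  out <- lowpass_30(cont)
  mid <- 500:1500
  amp_ratio5 <- max(out$data[1, mid]) / max(s5[mid])
  expect_gt(amp_ratio5, 0.99)
  att100 <- 20 * log10(max(abs(s100[mid])) / max(abs(out$data[2, mid])))
  expect_gt(att100, 20)
  # zero phase: cross-correlation of filtered vs clean 5 Hz peaks at lag 0
  cc <- stats::ccf(out$data[1, mid], s5[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("SOBI recovers sinusoidal sources mixed by a random matrix", {
  set.seed(42)
  t <- seq_len(5000) / 1000
  S <- rbind(sin(2 * pi * 3 * t), sin(2 * pi * 7 * t), sin(2 * pi * 13 * t))
  A <- matrix(rnorm(9), 3, 3)
  m <- sobi_fit(A %*% S, fs = 1000)
  rec <- m$unmixing %*% (A %*% S - rowMeans(A %*% S))
  corr <- abs(stats::cor(t(rec), t(S)))
  # best match per true source, up to permutation and sign
  expect_true(all(apply(corr, 2, max) > 0.95))
  # joint-diagonalization objective decreases monotonically over sweeps
  expect_true(all(diff(m$off_history) <= 1e-8))
})

test_that("SOBI leaves already separated sources untouched up to permutation and sign", {
  set.seed(7)
  # mutually independent AR(1) sources with distinct autocorrelation,
  # observed through the identity mixing
  S <- rbind(as.numeric(stats::arima.sim(list(ar = 0.9), 20000)),
             as.numeric(stats::arima.sim(list(ar = 0.3), 20000)),
             as.numeric(stats::arima.sim(list(ar = -0.7), 20000)))
  m <- sobi_fit(S, fs = 1000)
  rec <- m$unmixing %*% (S - rowMeans(S))
  corr <- abs(stats::cor(t(rec), t(S)))
  expect_true(all(apply(corr, 2, max) > 0.95))
  expect_error(sobi_fit(S[1, , drop = FALSE]), "2 channels")
})

test_that("rank-deficient input is refused", {
  X <- matrix(rnorm(1000), 2, 500)
  X <- rbind(X, X[1, ] + X[2, ])
  expect_error(sobi_fit(X, fs = 1000), "rank-deficient")
})

test_that("blink removal cleans frontal channels and preserves neural sources", {
  ev <- tibble::tibble(onset_ms = seq(500, 28000, by = 1100),
                       contour = FALSE, context = "iso",
                       subject = 1, condition = "no-contour/iso")
  cont <- simulate_continuous(layout_p, ev, noise_rms = 6, blink_rate = 30,
                              seed = 7)
  cont0 <- simulate_continuous(layout_p, ev, noise_rms = 6, blink_rate = 0,
                               seed = 7)  # same noise, no blinks
  model <- sobi_fit(cont)
  clean <- remove_blinks(cont, model)
  expect_gte(length(attr(clean, "blink_components")), 1)
  fr <- match(c("Fpz", "Fp1", "Fp2", "AFz"), cont$channels)
  win <- unlist(lapply(round(cont$blink_truth$onset_ms),
                       function(o) o:(o + 299)))
  win <- win[win <= ncol(cont$data) & win >= 1]
  rms <- function(x) sqrt(mean(x^2))
  before <- rms(cont$data[fr, win] - cont0$data[fr, win])
  after <- rms(clean$data[fr, win] - cont0$data[fr, win])
  expect_gte(1 - after / before, 0.8)
  # the posterior signal is preserved
  oz <- match("Oz", cont$channels)
  expect_gt(stats::cor(clean$data[oz, ], cont0$data[oz, ]), 0.98)
})

test_that("blink-free data pass through blink removal nearly unchanged", {
  ev <- tibble::tibble(onset_ms = seq(500, 15000, by = 1100),
                       contour = FALSE, context = "iso",
                       subject = 1, condition = "no-contour/iso")
  cont <- simulate_continuous(layout_p, ev, noise_rms = 6, blink_rate = 0,
                              seed = 8)
  model <- sobi_fit(cont)
  expect_warning(clean <- remove_blinks(cont, model), "threshold")
  rms_change <- sqrt(mean((clean$data - cont$data)^2)) /
    sqrt(mean(cont$data^2))
  expect_lt(rms_change, 0.02)
})

test_that("epoching slices 800 samples and baseline-corrects exactly", {
  set.seed(3)
  X <- matrix(rnorm(4 * 5000, sd = 5), 4, 5000)
  ev <- tibble::tibble(onset_ms = c(400, 1500, 3000, 4700))
  cont <- make_cont(X, c("a", "b", "c", "d"), events = ev)
  ep <- epoch_and_baseline(cont)
  # the 4700 ms event runs past the recording end and is skipped
  expect_equal(dim(ep$data), c(3, 4, 800))
  expect_equal(attr(ep, "skipped"), 1)
  expect_equal(ep$time[1], -200)
  expect_equal(ep$time[800], 599)
  bl <- apply(ep$data[, , 1:200], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # index-arithmetic oracle: epoch 2 = direct slice minus its baseline
  sl <- X[, (1500 - 200 + 1):(1500 + 600)]
  sl <- sl - rowMeans(sl[, 1:200])
  expect_equal(ep$data[2, , ], sl, tolerance = 1e-12)
})

test_that("artifact rejection drops epochs strictly exceeding 100 uV", {
  time <- 0:99
  n <- 10
  data <- array(stats::rnorm(n * 2 * 100, sd = 5), c(n, 2, 100))
  data[2, 1, 50] <- 150
  data[5, 2, 10] <- -150
  data[8, 1, 70] <- 150
  data[9, 2, 30] <- 100          # exactly at threshold: retained
  meta <- tibble::tibble(subject = 1, condition = "x", trial = 1:n)
  ep <- eeg_epochs(data, c("a", "b"), time, 1000, meta)
  out <- reject_artifacts(ep, 100)
  expect_equal(attr(out, "rejected"), c(2, 5, 8))
  expect_equal(dim(out$data)[1], 7)
  expect_true(9 %in% out$meta$trial)
  log <- attr(out, "rejection_log")
  expect_equal(log$n_in, 10)
  expect_equal(log$n_out, 7)
})

test_that("rejection separates simulated artifact epochs perfectly at well-separated amplitudes", {
  ep <- simulate_subject(layout_p, n_trials = 12, noise_rms = 5,
                         artifact_prob = 0.25, seed = 9)
  out <- reject_artifacts(ep, 100)
  truth <- ep$meta$artifact_truth
  rejected <- seq_len(nrow(ep$meta)) %in% attr(out, "rejected")
  sens <- sum(rejected & truth) / sum(truth)
  spec <- sum(!rejected & !truth) / sum(!truth)
  expect_gte(sum(truth), 1)
  expect_equal(sens, 1)
  expect_equal(spec, 1)
})

test_that("all-epochs-rejected is an explicit error", {
  data <- array(500, c(3, 2, 10))
  meta <- tibble::tibble(subject = 1, condition = "x", trial = 1:3)
  ep <- eeg_epochs(data, c("a", "b"), 0:9, 1000, meta)
  expect_error(reject_artifacts(ep), "all epochs")
})

test_that("robust averaging matches the arithmetic mean on clean data and resists outliers", {
  set.seed(11)
  n_tr <- 20
  clean_mean <- matrix(0, 2, 100)
  data <- array(stats::rnorm(n_tr * 2 * 100, sd = 1), c(n_tr, 2, 100))
  meta <- tibble::tibble(subject = 1, condition = "c1", trial = 1:n_tr)
  ep <- eeg_epochs(data, c("a", "b"), 0:99, 1000, meta)
  r <- robust_average(ep)
  p <- plain_average(ep)
  expect_lt(sqrt(mean((r$data - p$data)^2)), 0.1)

  # one grossly contaminated trial
  data2 <- data
  data2[7, 1, 40:60] <- data2[7, 1, 40:60] + 80
  ep2 <- eeg_epochs(data2, c("a", "b"), 0:99, 1000, meta)
  r2 <- robust_average(ep2)
  p2 <- plain_average(ep2)
  at <- 40:60
  err_robust <- abs(r2$data[1, 1, at] - clean_mean[1, at])
  err_plain <- abs(p2$data[1, 1, at] - clean_mean[1, at])
  expect_true(mean(err_robust) < mean(err_plain))
  # the contaminated samples of the outlier trial get weight < 0.1
  w <- attr(contourerp:::robust_mean_trials(data2), "weights")
  expect_true(all(w[7, 1, 45:55] < 0.1))
})

test_that("count equalization trims every cell to the global minimum", {
  set.seed(5)
  counts <- c(12, 9, 11, 10)
  conds <- rep(c("a", "b", "c", "d"), counts)
  n <- length(conds)
  data <- array(stats::rnorm(n * 2 * 10), c(n, 2, 10))
  meta <- tibble::tibble(subject = 1, condition = conds, trial = seq_len(n))
  ep <- eeg_epochs(data, c("x", "y"), 0:9, 1000, meta)
  eq <- equalize_counts(ep, seed = 1)
  expect_true(all(table(eq$meta$condition) == 9))
  # already equal: unchanged
  eq2 <- equalize_counts(eq, seed = 2)
  expect_equal(eq2$meta, eq$meta)
  # different seeds keep identical counts but different subsets
  eqA <- equalize_counts(ep, seed = 1)
  eqB <- equalize_counts(ep, seed = 99)
  expect_equal(table(eqA$meta$condition), table(eqB$meta$condition))
  expect_false(identical(eqA$meta$trial, eqB$meta$trial))
})

test_that("the noiseless chain preserves the ERP to within 1% RMS", {
  ev <- tidyr::expand_grid(contour = c(FALSE, TRUE),
                           context = c("iso", "random"), trial = 1:2)
  ev$subject <- 1
  ev$condition <- paste0(ifelse(ev$contour, "contour", "no-contour"),
                         "/", ev$context)
  ev$onset_ms <- 500 + (seq_len(nrow(ev)) - 1) * 1200
  cont <- simulate_continuous(layout_p, ev, noise_rms = 0, blink_rate = 0,
                              seed = 5)
  pp <- preprocess_pipeline(cont, sobi = FALSE)
  # reconstruct the expected noiseless ERP per cell directly
  pars <- cell_parameters()
  topo <- component_topography(layout_p)
  tt <- pp$erps_full$time
  for (i in seq_len(nrow(pp$erps_full$meta))) {
    p <- pars[pars$contour == pp$erps_full$meta$contour[i] &
                pars$context == pp$erps_full$meta$context[i], ]
    pred <- matrix(0, length(topo), length(tt))
    for (k in seq_len(nrow(p))) {
      pred <- pred + p$amplitude_uv[k] * topo %o%
        exp(-(tt - p$latency_ms[k])^2 / (2 * p$width_ms[k]^2))
    }
    # mastoid reference, the 30 Hz passband response and the baseline are
    # part of the chain's definition, so apply them to the prediction too
    pred <- sweep(pred, 2, colMeans(pred[match(c("M1", "M2"),
                                               names(topo)), ]))
    bf <- signal::butter(4, 30 / 500, type = "low")
    pred <- t(apply(pred, 1, function(x) signal::filtfilt(bf, x)))
    pred <- pred - rowMeans(pred[, tt < 0])
    got <- pp$erps_full$data[i, , ]
    interior <- tt > -150 & tt < 550   # exclude filter edge effects
    rel <- sqrt(mean((got[, interior] - pred[, interior])^2)) /
      sqrt(mean(pred[, interior]^2))
    expect_lt(rel, 0.01)
  }
})
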