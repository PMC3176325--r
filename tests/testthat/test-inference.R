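layout_i <- make_layout()

make_erpset <- function(waves, channels, time, meta) {
  erp_set(waves, channels, time, 1000, meta)
}

test_that("ROI averaging equals direct recomputation and collapses identical channels", {
  set.seed(1)
  time <- -200:599
  meta <- tidyr::expand_grid(subject = 1:2, contour = c(FALSE, TRUE),
                             context = c("iso", "random"))
  meta$condition <- paste0(ifelse(meta$contour, "contour", "no-contour"),
                           "/", meta$context)
  nch <- length(layout_i$channels$label)
  data <- array(stats::rnorm(nrow(meta) * nch * length(time)),
                c(nrow(meta), nch, length(time)))
  erps <- make_erpset(data, layout_i$channels$label, time, meta)
  w <- roi_average(erps, layout_i)
  # direct mean oracle
  ci <- match(layout_i$roi15, erps$channels)
  for (i in c(1, 5)) {
    direct <- colMeans(data[i, ci, ])
    got <- w$amplitude[w$subject == meta$subject[i] &
                         w$condition == meta$condition[i]]
    expect_equal(got, direct, tolerance = 1e-12)
  }
  # identical channels: roi average equals any single channel
  data2 <- data
  for (ch in seq_len(nch)) data2[, ch, ] <- data[, 1, ]
  erps2 <- make_erpset(data2, layout_i$channels$label, time, meta)
  w2 <- roi_average(erps2, layout_i)
  one <- data2[1, 1, ]
  expect_equal(w2$amplitude[w2$subject == 1 &
                              w2$condition == meta$condition[1]],
               one, tolerance = 1e-12)
  expect_error(roi_average(erps, layout_i, roi = c("Oz", "NOPE")), "NOPE")
})

test_that("difference waves vanish for identical conditions", {
  time <- 0:9
  meta <- tidyr::expand_grid(subject = 1, contour = c(FALSE, TRUE),
                             context = c("iso", "random"))
  meta$condition <- paste0(ifelse(meta$contour, "contour", "no-contour"),
                           "/", meta$context)
  w <- tidyr::expand_grid(meta, time_ms = time)
  w$amplitude <- sin(w$time_ms)          # same wave in all conditions
  d <- difference_waves(w)
  expect_true(all(abs(d$amplitude) < 1e-12))
})

test_that("component measures find constructed peaks, obey polarity, and break ties early", {
  time <- -200:599
  mk_wave <- function(f) tibble::tibble(
    subject = 1, condition = "contour/iso", contour = TRUE, context = "iso",
    time_ms = time, amplitude = f(time)
  )
  # Gaussian trough at 162 ms inside the N1 window
  w <- mk_wave(function(t) -5 * exp(-(t - 162)^2 / (2 * 15^2)))
  m <- component_measures(w)
  expect_equal(m$peak_latency_ms[m$component == "N1"], 162)
  # flat zero: amplitudes 0, latency at the window start (earliest tie)
  wz <- mk_wave(function(t) rep(0, length(t)))
  mz <- component_measures(wz)
  expect_true(all(mz$mean_amplitude == 0))
  expect_equal(mz$peak_latency_ms, component_windows()$lo_ms)
  # brute-force scan oracle on a random wave
  set.seed(4)
  wr <- mk_wave(function(t) stats::rnorm(length(t)))
  mr <- component_measures(wr)
  for (k in seq_len(nrow(component_windows()))) {
    win <- component_windows()[k, ]
    sel <- wr$time_ms >= win$lo_ms & wr$time_ms <= win$hi_ms
    expect_equal(mr$mean_amplitude[mr$component == win$component],
                 mean(wr$amplitude[sel]), tolerance = 1e-12)
    vals <- win$polarity * wr$amplitude[sel]
    expect_equal(mr$peak_latency_ms[mr$component == win$component],
                 wr$time_ms[sel][which.max(vals)])
  }
  # a window outside the epoch is an error
  short <- w[w$time_ms >= 0 & w$time_ms <= 100, ]
  expect_error(component_measures(short), "window")
})

test_that("the ANOVA uses denominator df 33 for 12 subjects x 4 cells", {
  m <- make_measures(function(s, c, x) rnorm(length(s)),
                     function(s, c, x) rnorm(length(s)))
  a <- rm_anova_sandwich(m)
  expect_true(all(a$df1 == 1))
  expect_true(all(a$df2 == 33))
  expect_equal(nrow(a), 6)     # 1 component x 2 measures x 3 terms
})

test_that("zero-effect data with subject offsets yield no spurious extreme effects", {
  m <- make_measures(
    function(s, c, x) 10 * s + rnorm(length(s), 0, 1e-3),
    function(s, c, x) 100 + 5 * s + rnorm(length(s), 0, 1e-3),
    seed = 3
  )
  a <- rm_anova_sandwich(m)
  expect_true(all(a$p > 1e-4))
})

test_that("unbalanced tables are rejected", {
  m <- make_measures(function(s, c, x) rnorm(length(s)),
                     function(s, c, x) rnorm(length(s)))
  expect_error(rm_anova_sandwich(m[-1, ]), "unbalanced")
})

test_that("the classical F branch equals a hand-computed sums-of-squares oracle", {
  for (seed in 1:3) {
    m <- make_measures(function(s, c, x) rnorm(length(s)),
                       function(s, c, x) rnorm(length(s)), seed = seed)
    a <- rm_anova_sandwich(m)
    amp <- a[a$measure == "mean amplitude", ]
    d <- data.frame(subject = m$subject, A = m$contour,
                    B = m$context, y = m$mean_amplitude)
    o <- oracle_rm_anova(d)
    expect_equal(amp$F_classical[amp$term == "contour"], o$F_A,
                 tolerance = 1e-8)
    expect_equal(amp$F_classical[amp$term == "context"], o$F_B,
                 tolerance = 1e-8)
    expect_equal(amp$F_classical[amp$term == "interaction"], o$F_AB,
                 tolerance = 1e-8)
  }
})

test_that("the interaction F grows with the injected interaction effect", {
  med_F <- vapply(c(0, 1, 2, 4), function(delta) {
    Fs <- vapply(1:8, function(rep) {
      m <- make_measures(
        function(s, c, x) -6 + rnorm(length(s), 0, 1) +
          delta * c * (x == "iso"),
        function(s, c, x) 149 + rnorm(length(s), 0, 4),
        seed = rep * 131 + delta * 7
      )
      a <- rm_anova_sandwich(m)
      a$F[a$measure == "mean amplitude" & a$term == "interaction"]
    }, numeric(1))
    stats::median(Fs)
  }, numeric(1))
  expect_true(all(diff(med_F) > 0))
})

test_that("a cohort recovers the injected 13 ms N1 latency shift within 4 ms", {
  tm <- seq(-200, 598, by = 2)
  lats <- vector("list", 12)
  for (s in 1:12) {
    ep <- simulate_subject(layout_i, n_trials = 30, noise_rms = 8,
                           seed = 400 + s, subject = s,
                           time = tm, fs = 500)
    erps <- plain_average(ep)
    m <- component_measures(roi_average(erps, layout_i))
    lats[[s]] <- m[m$component == "N1", c("contour", "peak_latency_ms")]
  }
  lat <- dplyr::bind_rows(lats)
  shift <- mean(lat$peak_latency_ms[lat$contour]) -
    mean(lat$peak_latency_ms[!lat$contour])
  expect_lt(abs(shift - 13), 4)
})
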