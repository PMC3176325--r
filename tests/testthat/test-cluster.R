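layout_c <- make_layout()
scalp_ch <- layout_c$channels$label[layout_c$channels$type == "scalp"]

rand_erp_pair <- function(n = 12, nch = 10, nt = 20, seed = 1,
                          channels = scalp_ch[seq_len(nch)]) {
  set.seed(seed)
  a <- array(stats::rnorm(n * nch * nt), c(n, nch, nt),
             dimnames = list(NULL, channels, NULL))
  b <- array(stats::rnorm(n * nch * nt), c(n, nch, nt),
             dimnames = list(NULL, channels, NULL))
  list(a = a, b = b)
}

test_that("pointwise paired t matches the textbook formula and handles degenerate input", {
  d <- rand_erp_pair(n = 12, nch = 4, nt = 6, seed = 2)
  tm <- pointwise_paired_t(d$a, d$b)
  for (i in 1:4) for (j in 1:6) {
    expect_equal(tm[i, j], oracle_paired_t(d$a[, i, j], d$b[, i, j]),
                 tolerance = 1e-10)
  }
  # identical conditions: t = 0 everywhere (zero variance handled)
  expect_warning(t0 <- pointwise_paired_t(d$a, d$a), "zero variance")
  expect_true(all(t0 == 0))
  # constant offset with zero within-pair variance
  b2 <- d$a + 1
  expect_warning(tc <- pointwise_paired_t(d$a, b2), "zero variance")
  expect_true(all(tc == 0))
})

test_that("cluster formation equals brute-force flood fill on a chain adjacency", {
  # hand-built 3-channel chain (a-b-c) x 5 samples
  chain <- matrix(FALSE, 3, 3,
                  dimnames = list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  chain["x1", "x2"] <- chain["x2", "x1"] <- TRUE
  chain["x2", "x3"] <- chain["x3", "x2"] <- TRUE
  lay <- list(adjacency = chain)
  tmap <- rbind(
    c(3,  0, 0, 3, 3),
    c(0,  0, 3, 0, 0),
    c(3,  0, 3, 0, -3)
  )
  rownames(tmap) <- c("x1", "x2", "x3")
  cl <- form_clusters(tmap, lay, t_threshold = 2)
  lab <- oracle_components(tmap > 2, chain)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  oracle_sets <- lapply(ids, function(id) sort(which(lab == id)))
  got_sets <- lapply(which(cl$polarity == "positive"), function(i) {
    m <- cl$members[[i]]
    sort((m$time_index - 1) * 3 + m$channel_index)
  })
  expect_setequal(lapply(got_sets, paste, collapse = ","),
                  lapply(oracle_sets, paste, collapse = ","))
  # negative point forms its own single-point cluster, polarity separated
  neg <- cl[cl$polarity == "negative", ]
  expect_equal(nrow(neg), 1)
  expect_equal(neg$n_points, 1)
  expect_equal(neg$mass, -3)
})

test_that("a single supra-threshold point is a cluster of size one with mass t", {
  adj <- matrix(FALSE, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  lay <- list(adjacency = adj)
  tmap <- matrix(c(0, 0, 5, 0), 2, 2, dimnames = list(c("p", "q"), NULL))
  cl <- form_clusters(tmap, lay, 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_points, 1)
  expect_equal(cl$mass, 5)
})

test_that("adjacent positive and negative points never merge", {
  adj <- matrix(FALSE, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  adj["p", "q"] <- adj["q", "p"] <- TRUE
  lay <- list(adjacency = adj)
  tmap <- matrix(c(5, -5, 5, -5), 2, 2, dimnames = list(c("p", "q"), NULL))
  cl <- form_clusters(tmap, lay, 2)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$polarity, c("positive", "negative"))
})

test_that("the permutation test is exact and reproducible for 12 subjects", {
  d <- rand_erp_pair(n = 12, nch = 8, nt = 12, seed = 5)
  r1 <- permutation_test(d$a, d$b, layout_c)
  r2 <- permutation_test(d$a, d$b, layout_c)
  expect_true(r1$exact)
  expect_equal(r1$n_perm, 4096)
  expect_identical(r1$clusters$p, r2$clusters$p)
  expect_true(all(r1$clusters$p > 0 & r1$clusters$p <= 1))
  expect_error(permutation_test(d$a, d$b, layout_c, n_perm = 50),
               "at least 100")
})

test_that("results are invariant under channel relabeling", {
  d <- rand_erp_pair(n = 12, nch = 6, nt = 10, seed = 6)
  perm <- c(3, 1, 6, 2, 5, 4)
  a2 <- d$a[, perm, ]
  b2 <- d$b[, perm, ]
  dimnames(a2)[[2]] <- dimnames(d$a)[[2]][perm]
  dimnames(b2)[[2]] <- dimnames(d$b)[[2]][perm]
  r1 <- permutation_test(d$a, d$b, layout_c)
  r2 <- permutation_test(a2, b2, layout_c)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass),
               tolerance = 1e-10)
  expect_equal(sort(r1$clusters$p), sort(r2$clusters$p))
})

test_that("scaling an injected effect up never shrinks the largest cluster mass", {
  set.seed(9)
  n <- 12; nch <- 8; nt <- 15
  channels <- scalp_ch[seq_len(nch)]
  noise_a <- array(stats::rnorm(n * nch * nt), c(n, nch, nt),
                   dimnames = list(NULL, channels, NULL))
  noise_b <- array(stats::rnorm(n * nch * nt), c(n, nch, nt),
                   dimnames = list(NULL, channels, NULL))
  effect <- array(0, c(n, nch, nt))
  effect[, 1:4, 5:10] <- 1
  masses <- vapply(c(0.5, 1, 2, 4), function(scale) {
    a <- noise_a + scale * effect
    r <- permutation_test(a, noise_b, layout_c)
    max(abs(r$clusters$mass))
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("tidy and glance summarize cluster results", {
  d <- rand_erp_pair(n = 12, nch = 6, nt = 10, seed = 10)
  r <- permutation_test(d$a, d$b, layout_c)
  td <- tidy(r)
  expect_true(all(c("cluster", "polarity", "mass", "p", "significant")
                  %in% names(td)))
  g <- glance(r)
  expect_equal(g$n_clusters, nrow(td))
  expect_true(g$exact)
})
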