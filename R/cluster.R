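#' Pointwise paired t statistics over channels x time
#'
#' Paired t across subjects at every channel x time point. Points with
#' zero within-pair variance get t = 0 with a warning (the statistic is
#' undefined there).
#'
#' @param a,b numeric arrays `subjects x channels x time`, matched
#'   subject order.
#' @return numeric matrix channels x time of t values.
#' @export
pointwise_paired_t <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)), dim(a)[1] >= 3)
  d <- a - b
  n <- dim(d)[1]
  D <- matrix(d, nrow = n)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  zero <- v <= 1e-24 | !is.finite(v)
  if (any(zero)) {
    warning(sum(zero), " points with zero variance; t set to 0")
    v[zero] <- Inf
  }
  matrix(m / sqrt(v / n), dim(d)[2], dim(d)[3])
}

#' Form spatiotemporal clusters from a thresholded t map
#'
#' Supra-threshold points of one polarity are linked when they share a
#' time sample and sit on neighbouring channels, or share a channel and
#' sit on consecutive samples. Positive and negative clusters never
#' merge. Cluster mass is the sum of t values over members.
#'
#' @param tmap channels x time t matrix; rows must be named with channel
#'   labels present in the layout (or supply `channels`).
#' @param layout a `sensor_layout`.
#' @param t_threshold cluster-forming threshold (> 0).
#' @param channels channel labels for the rows of `tmap`.
#' @return tibble of class `cluster_set`: columns `cluster`, `polarity`,
#'   `mass`, `n_points`, `members` (list of tibbles channel/time index).
#' @export
form_clusters <- function(tmap, layout, t_threshold, channels = rownames(tmap)) {
  stopifnot(t_threshold > 0)
  if (is.null(channels)) stop("channel labels needed to look up adjacency")
  adj <- layout$adjacency[channels, channels]
  nch <- nrow(tmap)
  out <- list()
  for (pol in c(1, -1)) {
    lab <- cluster_label_cpp(tmap, adj, t_threshold, pol)
    sel <- which(lab > 0)
    if (!length(sel)) next
    by_id <- split(sel, lab[sel])
    for (idx in by_id) {
      ci <- (idx - 1L) %% nch + 1L
      ti <- (idx - 1L) %/% nch + 1L
      out[[length(out) + 1]] <- tibble::tibble(
        polarity = if (pol > 0) "positive" else "negative",
        mass = sum(tmap[idx]),
        n_points = length(idx),
        members = list(tibble::tibble(channel = channels[ci],
                                      channel_index = ci,
                                      time_index = ti))
      )
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(polarity = character(), mass = numeric(),
                   n_points = integer(), members = list())
  res <- res[order(-abs(res$mass)), ]
  res <- dplyr::mutate(res, cluster = dplyr::row_number(), .before = 1)
  class(res) <- c("cluster_set", class(res))
  res
}

#' Spatiotemporal cluster-based permutation test (paired design)
#'
#' Tests whether two within-subject conditions differ anywhere over
#' channels x time while controlling the familywise error by clustering.
#' The null distribution of the maximum cluster mass is built by random
#' sign flips of the per-subject difference waves -- exhaustively over
#' all `2^n` sign patterns when `2^n <= n_perm` (for 12 subjects,
#' exactly 4096 patterns, making the test fully deterministic),
#' otherwise by `n_perm` Monte Carlo draws (with +1 smoothing in the
#' p value so p is never 0).
#'
#' Each observed cluster is compared to the null maxima of its own
#' polarity; with the two polarity tails, a cluster is flagged
#' significant when its p value is at most `alpha/2`.
#'
#' @param a,b numeric arrays `subjects x channels x time` (channel
#'   dimension named, or supply `channels`).
#' @param layout a `sensor_layout`.
#' @param n_perm permutation budget (>= 100).
#' @param seed integer seed (used only in the Monte Carlo branch).
#' @param alpha familywise significance level.
#' @param t_threshold cluster-forming threshold; default is the
#'   two-sided 5% t quantile at `n - 1` degrees of freedom.
#' @param channels channel labels of the second array dimension.
#' @return object of class `cluster_result`: list with `clusters`
#'   (tibble incl. `p` and `significant`), `tmap`, `t_threshold`,
#'   `n_perm`, `exact`, `null_max` (matrix of per-permutation extreme
#'   masses).
#' @export
permutation_test <- function(a, b, layout, n_perm = 4096, seed = 1,
                             alpha = 0.05, t_threshold = NULL,
                             channels = dimnames(a)[[2]]) {
  stopifnot(identical(dim(a), dim(b)))
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  n <- dim(a)[1]
  if (is.null(channels)) stop("channel labels needed")
  nch <- dim(a)[2]; nt <- dim(a)[3]
  adj <- layout$adjacency[channels, channels]
  if (is.null(t_threshold)) t_threshold <- stats::qt(0.975, n - 1)

  d <- a - b
  D <- matrix(d, nrow = n)                 # subjects x (nch*nt)
  exact <- 2^n <= n_perm
  if (exact) {
    S <- 2^n
    signs <- matrix(1, S, n)
    for (j in seq_len(n)) {
      signs[, j] <- ifelse(bitwAnd(seq_len(S) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                           -1, 1)
    }
  } else {
    set.seed(seed)
    S <- n_perm
    signs <- matrix(sample(c(-1, 1), S * n, replace = TRUE), S, n)
  }
  ss <- colSums(D^2)                        # invariant under sign flips
  Mt <- t(D) %*% t(signs) / n               # P x S, columns contiguous
  v <- (ss - n * Mt^2) / (n - 1)            # ss recycles down columns
  v[v <= 1e-24] <- Inf
  Tmat <- Mt / sqrt(v / n)
  null_max <- perm_max_mass_cpp(Tmat, nch, nt, adj, t_threshold)

  tmap <- suppressWarnings(pointwise_paired_t(a, b))
  rownames(tmap) <- channels
  clusters <- form_clusters(tmap, layout, t_threshold, channels)
  if (nrow(clusters)) {
    clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
      if (clusters$polarity[i] == "positive") {
        hits <- sum(null_max[, 1] >= clusters$mass[i])
      } else {
        hits <- sum(null_max[, 2] <= clusters$mass[i])
      }
      if (exact) hits / S else (1 + hits) / (1 + S)
    }, numeric(1))
    clusters$significant <- clusters$p <= alpha / 2
  } else {
    clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, tmap = tmap,
                 t_threshold = t_threshold, n_perm = S, exact = exact,
                 alpha = alpha, null_max = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " cluster(s); threshold |t| > ",
      round(x$t_threshold, 3), "; ",
      if (x$exact) "exact enumeration of " else "Monte Carlo with ",
      x$n_perm, " sign patterns\n", sep = "")
  if (nrow(x$clusters)) {
    print(dplyr::select(tibble::as_tibble(x$clusters), -"members"))
  }
  invisible(x)
}

#' Per-subject condition arrays for a contrast
#'
#' Collapses an `erp_set` to `subjects x channels x time` arrays for two
#' condition groups (averaging within subject over the conditions in
#' each group), e.g. contour vs no-contour pooled over context.
#'
#' @param erps an `erp_set`.
#' @param group_a,group_b character vectors of condition labels.
#' @param channels channels to keep (default: all but mastoids and EOG,
#'   i.e. the channels the cluster test's adjacency covers).
#' @return list of two arrays `a` and `b` with channel dimnames.
#' @export
condition_arrays <- function(erps,
                             group_a = c("contour/iso", "contour/random"),
                             group_b = c("no-contour/iso",
                                         "no-contour/random"),
                             channels = NULL) {
  stopifnot(inherits(erps, "erp_set"))
  channels <- channels %||%
    setdiff(erps$channels, c("M1", "M2", "VEOG", "HEOG"))
  ci <- match(channels, erps$channels)
  if (anyNA(ci)) stop("unknown channel(s) requested")
  subjects <- sort(unique(erps$meta$subject))
  nt <- dim(erps$data)[3]
  collapse <- function(group) {
    out <- array(0, c(length(subjects), length(ci), nt),
                 dimnames = list(NULL, channels, NULL))
    for (si in seq_along(subjects)) {
      rows <- which(erps$meta$subject == subjects[si] &
                      erps$meta$condition %in% group)
      if (!length(rows)) stop("missing conditions for subject ", subjects[si])
      out[si, , ] <- apply(erps$data[rows, ci, , drop = FALSE], c(2, 3), mean)
    }
    out
  }
  list(a = collapse(group_a), b = collapse(group_b))
}
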