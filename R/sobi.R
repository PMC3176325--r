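#' Second-order blind source identification (SOBI)
#'
#' Separates sources with distinct autocorrelation structure by (1)
#' whitening the data through an eigendecomposition of the zero-lag
#' covariance and (2) jointly approximately diagonalizing a set of
#' time-lagged covariance matrices with a Jacobi rotation scheme
#' (Cardoso-Souloumiac pairwise rotations). Blink activity, with its slow
#' stereotyped autocorrelation, separates reliably from neural background
#' under this criterion.
#'
#' @param x an `eeg_continuous` or a numeric matrix (channels x samples);
#'   rows are centered internally.
#' @param lags_ms lags of the covariance set, in ms. The default covers
#'   1--100 ms in 15 log-spaced steps, spanning blink autocorrelation
#'   timescales.
#' @param fs sampling rate (taken from `x` when it is a container).
#' @param channels which rows to model when `x` is a container; defaults
#'   to the scalp channels.
#' @param tol rotation angle tolerance stopping the Jacobi sweeps.
#' @param max_sweeps maximum number of full sweeps.
#' @return object of class `sobi_model`: `sphering` (whitening matrix),
#'   `rotation` (orthogonal), `unmixing` (components x channels),
#'   `mixing` (channels x components, columns normalized),
#'   `channels`, `lags` (samples), and `off_history` (summed
#'   off-diagonal mass of the lagged covariance set after each sweep).
#' @export
sobi_fit <- function(x, lags_ms = unique(round(exp(seq(log(1), log(100),
                                                       length.out = 15)))),
                     fs = NULL, channels = NULL, tol = 1e-6,
                     max_sweeps = 100) {
  if (inherits(x, "eeg_continuous")) {
    if (is.null(fs)) fs <- x$fs
    if (is.null(channels)) {
      channels <- x$channels[!x$channels %in% c("M1", "M2", "VEOG", "HEOG")]
    }
    X <- x$data[match(channels, x$channels), , drop = FALSE]
  } else {
    X <- x
    if (is.null(fs)) fs <- 1000
    if (is.null(channels)) channels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  }
  n <- nrow(X); T_ <- ncol(X)
  if (n < 2) stop("SOBI needs at least 2 channels")
  X <- X - rowMeans(X)
  C0 <- tcrossprod(X) / T_
  eg <- eigen(C0, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-12) {
    stop("rank-deficient covariance; cannot whiten")
  }
  sphering <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- sphering %*% X
  lags <- unique(pmax(1L, round(lags_ms * fs / 1000)))
  lags <- lags[lags < T_ - 1]
  K <- length(lags)
  M <- array(0, c(n, n, K))
  for (k in seq_len(K)) {
    tau <- lags[k]
    R <- Z[, 1:(T_ - tau), drop = FALSE] %*%
      t(Z[, (1 + tau):T_, drop = FALSE]) / (T_ - tau)
    M[, , k] <- (R + t(R)) / 2
  }
  jd <- joint_diagonalize(M, tol = tol, max_sweeps = max_sweeps)
  V <- jd$V
  unmixing <- t(V) %*% sphering
  mixing <- eg$vectors %*% diag(sqrt(eg$values)) %*% V
  cn <- sqrt(colSums(mixing^2))
  mixing <- sweep(mixing, 2, cn, "/")
  unmixing <- sweep(unmixing, 1, cn, "*")
  structure(list(sphering = sphering, rotation = V, unmixing = unmixing,
                 mixing = mixing, channels = channels, lags = lags,
                 off_history = jd$off_history),
            class = "sobi_model")
}

# Jacobi joint approximate diagonalization of the n x n x K array M.
joint_diagonalize <- function(M, tol = 1e-6, max_sweeps = 100) {
  n <- dim(M)[1]; K <- dim(M)[3]
  V <- diag(n)
  off <- function(M) {
    s <- 0
    for (k in seq_len(dim(M)[3])) {
      A <- M[, , k]
      s <- s + sum(A^2) - sum(diag(A)^2)
    }
    s
  }
  off_history <- numeric(0)
  for (sweep_i in seq_len(max_sweeps)) {
    max_s <- 0
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        g1 <- M[p, p, ] - M[q, q, ]
        g2 <- M[p, q, ] + M[q, p, ]
        ton <- sum(g1 * g1) - sum(g2 * g2)
        toff <- 2 * sum(g1 * g2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        cs <- cos(theta); sn <- sin(theta)
        if (abs(sn) > tol) {
          max_s <- max(max_s, abs(sn))
          rp <- M[p, , ]; rq <- M[q, , ]          # rows, n x K
          M[p, , ] <- cs * rp + sn * rq
          M[q, , ] <- -sn * rp + cs * rq
          cp <- M[, p, ]; cq <- M[, q, ]          # columns
          M[, p, ] <- cs * cp + sn * cq
          M[, q, ] <- -sn * cp + cs * cq
          vp <- V[, p]; vq <- V[, q]
          V[, p] <- cs * vp + sn * vq
          V[, q] <- -sn * vp + cs * vq
        }
      }
    }
    off_history <- c(off_history, off(M))
    if (max_s <= tol) break
  }
  list(V = V, off_history = off_history)
}

#' Remove blink components from continuous data
#'
#' Projects the data onto the SOBI components, zeroes every component
#' whose time course correlates with the vertical EOG beyond
#' `threshold` (at most `max_remove` components, taken in decreasing
#' correlation order), and back-projects.
#'
#' @param x an `eeg_continuous` containing a VEOG channel (or the
#'   channel supplied via `veog`).
#' @param model a fitted `sobi_model`.
#' @param veog optional numeric vector overriding the VEOG channel.
#' @param threshold absolute Pearson correlation above which a component
#'   counts as ocular.
#' @param max_remove maximum number of components to remove.
#' @return `x` with the modelled channels cleaned; attribute
#'   `blink_components` lists the removed component indices (empty, with
#'   a warning, when none exceeded the threshold).
#' @export
remove_blinks <- function(x, model, veog = NULL, threshold = 0.6,
                          max_remove = 2) {
  stopifnot(inherits(x, "eeg_continuous"), inherits(model, "sobi_model"))
  if (is.null(veog)) {
    if (!"VEOG" %in% x$channels) stop("no VEOG channel available")
    veog <- x$data[match("VEOG", x$channels), ]
  }
  idx <- match(model$channels, x$channels)
  X <- x$data[idx, , drop = FALSE]
  ctr <- rowMeans(X)
  S <- model$unmixing %*% (X - ctr)
  r <- abs(apply(S, 1, stats::cor, y = veog))
  bad <- which(r > threshold)
  if (length(bad) == 0) {
    warning("no component exceeded the VEOG correlation threshold; ",
            "data returned unchanged")
    attr(x, "blink_components") <- integer(0)
    return(x)
  }
  bad <- bad[order(r[bad], decreasing = TRUE)][seq_len(min(length(bad),
                                                           max_remove))]
  S[bad, ] <- 0
  x$data[idx, ] <- model$mixing %*% S + ctr
  attr(x, "blink_components") <- bad
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
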