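# Independent brute-force oracles used to cross-check package
# implementations. These deliberately use the most literal algorithm
# available (all-pairs scans, ray casting, flood fill) and share no code
# with the package internals.

# do segments p1-p2 and p3-p4 properly intersect? (shared endpoints of
# adjacent polyline segments are not counted)
segs_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# brute-force all-segment-pairs self-intersection test of a closed
# polyline (first vertex not repeated)
oracle_self_intersects <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (shared endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segs_intersect(poly[i, ], poly[nxt[i], ],
                         poly[j, ], poly[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# ray-casting point-in-polygon (horizontal ray to +x)
oracle_inside <- function(poly, pts) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  apply(pts, 1, function(p) {
    crossings <- 0
    for (i in 1:n) {
      a <- poly[i, ]; b <- poly[nxt[i], ]
      if ((a[2] > p[2]) != (b[2] > p[2])) {
        xint <- a[1] + (p[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
        if (xint > p[1]) crossings <- crossings + 1
      }
    }
    crossings %% 2 == 1
  })
}

# all-pairs mean k-NN distance per point (px), neighbours over all points
oracle_knn_mean <- function(xy, k = 5) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in 1:n) {
    d <- numeric(n - 1)
    m <- 0
    for (j in 1:n) {
      if (i == j) next
      m <- m + 1
      d[m] <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
    }
    out[i] <- mean(sort(d)[1:k])
  }
  out
}

# per-region mean 5-NN distance in arcmin, fully independent of the
# package implementation
oracle_density_report <- function(field, px_per_arcmin = 496 / 840) {
  knn <- oracle_knn_mean(cbind(field$x, field$y), 5) / px_per_arcmin
  tm <- tapply(knn, field$region, mean)
  means <- stats::setNames(as.numeric(tm), names(tm))
  list(means = means, max_diff = max(abs(outer(means, means, "-"))))
}

# brute-force flood fill over a channels x time logical mask with an
# explicit channel adjacency matrix (same linking rule as the package:
# same-time neighbouring channels, same-channel adjacent samples)
oracle_components <- function(mask, adj) {
  nch <- nrow(mask); nt <- ncol(mask)
  label <- matrix(0L, nch, nt)
  id <- 0L
  for (c0 in 1:nch) {
    for (t0 in 1:nt) {
      if (!mask[c0, t0] || label[c0, t0] != 0L) next
      id <- id + 1L
      queue <- list(c(c0, t0))
      label[c0, t0] <- id
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        cc <- cur[1]; tt <- cur[2]
        for (t2 in c(tt - 1, tt + 1)) {
          if (t2 >= 1 && t2 <= nt && mask[cc, t2] && label[cc, t2] == 0L) {
            label[cc, t2] <- id
            queue[[length(queue) + 1]] <- c(cc, t2)
          }
        }
        for (c2 in which(adj[cc, ])) {
          if (mask[c2, tt] && label[c2, tt] == 0L) {
            label[c2, tt] <- id
            queue[[length(queue) + 1]] <- c(c2, tt)
          }
        }
      }
    }
  }
  label
}

# textbook paired t for one point
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / sqrt(stats::var(d) / length(d))
}

# balanced 2x2 within-subject ANOVA by explicit sums of squares
# d: subject, A (2 levels), B (2 levels), y; one observation per cell
oracle_rm_anova <- function(d) {
  subjects <- sort(unique(d$subject))
  As <- sort(unique(d$A)); Bs <- sort(unique(d$B))
  n <- length(subjects)
  gm <- mean(d$y)
  m_s <- function(s) mean(d$y[d$subject == s])
  m_a <- function(a) mean(d$y[d$A == a])
  m_b <- function(b) mean(d$y[d$B == b])
  m_ab <- function(a, b) mean(d$y[d$A == a & d$B == b])
  m_sa <- function(s, a) mean(d$y[d$subject == s & d$A == a])
  m_sb <- function(s, b) mean(d$y[d$subject == s & d$B == b])
  ssA <- 2 * n * sum(vapply(As, function(a) (m_a(a) - gm)^2, 0))
  ssB <- 2 * n * sum(vapply(Bs, function(b) (m_b(b) - gm)^2, 0))
  ssAB <- 0
  for (a in As) for (b in Bs) {
    ssAB <- ssAB + n * (m_ab(a, b) - m_a(a) - m_b(b) + gm)^2
  }
  ssSA <- 0
  for (s in subjects) for (a in As) {
    ssSA <- ssSA + 2 * (m_sa(s, a) - m_s(s) - m_a(a) + gm)^2
  }
  ssSB <- 0
  for (s in subjects) for (b in Bs) {
    ssSB <- ssSB + 2 * (m_sb(s, b) - m_s(s) - m_b(b) + gm)^2
  }
  ssSAB <- 0
  for (s in subjects) for (a in As) for (b in Bs) {
    y <- d$y[d$subject == s & d$A == a & d$B == b]
    ssSAB <- ssSAB + (y - m_sa(s, a) - m_sb(s, b) - m_ab(a, b) +
                        m_s(s) + m_a(a) + m_b(b) - gm)^2
  }
  list(
    F_A = ssA / (ssSA / (n - 1)),
    F_B = ssB / (ssSB / (n - 1)),
    F_AB = ssAB / (ssSAB / (n - 1))
  )
}

# small helper: manually constructed component_measures table
make_measures <- function(fun_amp, fun_lat, n_subjects = 12, seed = 1) {
  set.seed(seed)
  cells <- tidyr::expand_grid(subject = seq_len(n_subjects),
                              contour = c(FALSE, TRUE),
                              context = c("iso", "random"))
  out <- dplyr::mutate(
    cells,
    condition = paste0(ifelse(contour, "contour", "no-contour"), "/", context),
    component = "N1",
    mean_amplitude = fun_amp(subject, contour, context),
    peak_latency_ms = fun_lat(subject, contour, context)
  )
  class(out) <- c("component_measures", class(out))
  out
}
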