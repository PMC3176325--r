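#' Build the 64-channel sensor layout
#'
#' A fixed 64-electrode montage on the extended 10-5 naming scheme, plus
#' the two mastoids (M1, M2) and bipolar ocular channels (VEOG, HEOG).
#' Scalp positions are generated on a schematic sphere (polar angle from
#' the vertex, azimuth from the nasion) and projected azimuthally to 2-D,
#' which reproduces the familiar flat cap layout well enough for
#' neighbourhood definitions and topographies. The adjacency graph links
#' channels whose projected distance is below `neighbor_dist`.
#'
#' The 15-channel posterior region of interest used for component
#' analyses is Oz, O1, O2, PO3--PO8, and P3--P8.
#'
#' @param neighbor_dist adjacency distance threshold on the unit-radius
#'   projection.
#' @return an object of class `sensor_layout`: list with `channels`
#'   (tibble: label, x, y, type), `adjacency` (symmetric logical matrix
#'   over scalp channels), `roi15`, `mastoids`, `eog`.
#' @export
make_layout <- function(neighbor_dist = 0.26) {
  rows <- list(
    #       alpha_mid  psi_outer  front?  labels (midline, 1..7 pairs)
    Fp = list(72, 18,  TRUE,  c("Fpz", "Fp1", "Fp2")),
    AF = list(54, 36,  TRUE,  c("AFz", "AF3", "AF4", "AF7", "AF8")),
    F  = list(36, 54,  TRUE,  c("Fz", "F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8")),
    FC = list(18, 72,  TRUE,  c("FCz", "FC1", "FC2", "FC3", "FC4", "FC5", "FC6", "FT7", "FT8")),
    C  = list(0,  90,  TRUE,  c("Cz", "C1", "C2", "C3", "C4", "C5", "C6", "T7", "T8")),
    CP = list(18, 108, FALSE, c("CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6", "TP7", "TP8")),
    P  = list(36, 126, FALSE, c("Pz", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8")),
    PO = list(54, 144, FALSE, c("POz", "PO3", "PO4", "PO5", "PO6", "PO7", "PO8")),
    O  = list(72, 162, FALSE, c("Oz", "O1", "O2")),
    Iz = list(90, 180, FALSE, "Iz")
  )
  labs <- character(0); xs <- numeric(0); ys <- numeric(0)
  for (row in rows) {
    alpha_mid <- row[[1]]; psi_outer <- row[[2]]; front <- row[[3]]
    psi_mid <- if (front) 0 else 180
    for (lab in row[[4]]) {
      num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", lab)))
      if (is.na(num)) {             # midline (z) electrode
        f <- 0; side <- 0
      } else {
        side <- if (num %% 2 == 1) -1 else 1   # odd left, even right
        lat <- ceiling(num / 2)                # 1..4 lateral index
        # rows whose outermost member is the '7/8' pair span f in (0,1];
        # the Fp and O rows only reach the outer ring itself
        f <- if (lab %in% c("Fp1", "Fp2", "O1", "O2")) 1 else lat / 4
      }
      alpha <- (1 - f) * alpha_mid + f * 72
      psi <- if (alpha_mid == 0 && f == 0) 0 else (1 - f) * psi_mid + f * psi_outer
      r <- alpha / 90
      labs <- c(labs, lab)
      xs <- c(xs, side * r * sin(psi * pi / 180))
      ys <- c(ys, r * cos(psi * pi / 180))
    }
  }
  scalp <- tibble::tibble(label = labs, x = xs, y = ys, type = "scalp")
  extra <- tibble::tibble(
    label = c("M1", "M2", "VEOG", "HEOG"),
    x = c(-1.05, 1.05, -0.18, 0.55),
    y = c(-0.35, -0.35, 1.05, 1.0),
    type = c("mastoid", "mastoid", "eog", "eog")
  )
  channels <- dplyr::bind_rows(scalp, extra)
  pos <- as.matrix(scalp[, c("x", "y")])
  d <- as.matrix(stats::dist(pos))
  adjacency <- d > 0 & d <= neighbor_dist
  # every channel keeps at least its two nearest neighbours, so outlying
  # electrodes (e.g. Iz) are never isolated from the graph
  for (i in seq_len(nrow(d))) {
    nn <- order(d[i, ])[2:3]
    adjacency[i, nn] <- TRUE
    adjacency[nn, i] <- TRUE
  }
  dimnames(adjacency) <- list(scalp$label, scalp$label)
  structure(
    list(
      channels = channels,
      adjacency = adjacency,
      roi15 = c("Oz", "O1", "O2", "PO3", "PO4", "PO5", "PO6", "PO7", "PO8",
                "P3", "P4", "P5", "P6", "P7", "P8"),
      mastoids = c("M1", "M2"),
      eog = c("VEOG", "HEOG")
    ),
    class = "sensor_layout"
  )
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> ", sum(x$channels$type == "scalp"),
      " scalp channels + ", sum(x$channels$type != "scalp"),
      " auxiliary; ", sum(x$adjacency) / 2, " adjacency edges\n", sep = "")
  invisible(x)
}

scalp_labels <- function(layout) {
  layout$channels$label[layout$channels$type == "scalp"]
}
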