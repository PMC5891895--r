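# Shared fixtures: tiny recordings and series built in code.

# single- or multi-channel recording from a numeric matrix (channels x samples)
make_recording <- function(x, fs, onsets = NULL, retrieval_index = NULL,
                           mastoids = character(0), positions = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  labels <- rownames(x) %||% paste0("c", seq_len(nrow(x)))
  rownames(x) <- labels
  if (is.null(positions)) {
    positions <- cbind(seq_len(nrow(x)), 0, 0)
    rownames(positions) <- labels
  }
  structure(list(channel_labels = labels, positions = positions,
                 fs_hz = fs, data = x,
                 annotations = list(retrieval_onsets = onsets,
                                    retrieval_index = retrieval_index,
                                    artifact_spans = NULL,
                                    bad_channels = character(0),
                                    mastoids = mastoids),
                 duration_s = ncol(x) / fs),
            class = "eeg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal retrieval series with constant routes
make_series <- function(durations, route = "R1", units = NULL,
                        x2 = 3, z2 = 4, distraction = FALSE) {
  n <- length(durations)
  df <- data.frame(index = seq_len(n),
                   route_label = rep_len(route, n),
                   x1 = 0, z1 = 0, x2 = x2, z2 = z2,
                   start_time_s = cumsum(c(0, durations[-n])),
                   duration_s = durations,
                   units = units %||% rep(5.5, n),
                   distraction = rep_len(distraction, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("retrieval_series", "data.frame")
  df
}

# brute-force best segmentation with exactly k breaks (for oracle checks)
oracle_segmentation <- function(x, k, min_seg = 2L) {
  n <- length(x)
  cost <- function(seg) sum((seg - mean(seg))^2)
  best <- list(rss = Inf, breaks = NULL)
  if (k == 0) return(list(rss = cost(x), breaks = integer(0)))
  if (k == 1) {
    for (b in min_seg:(n - min_seg)) {
      r <- cost(x[1:b]) + cost(x[(b + 1):n])
      if (r < best$rss) best <- list(rss = r, breaks = b)
    }
  } else if (k == 2) {
    for (b1 in min_seg:(n - 2 * min_seg)) {
      for (b2 in (b1 + min_seg):(n - min_seg)) {
        r <- cost(x[1:b1]) + cost(x[(b1 + 1):b2]) + cost(x[(b2 + 1):n])
        if (r < best$rss) best <- list(rss = r, breaks = c(b1, b2))
      }
    }
  } else stop("oracle supports k <= 2")
  best
}

# direct DFT periodogram oracle (Hamming taper, one-sided density)
oracle_periodogram <- function(seg, fs) {
  n <- length(seg)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- seg * w
  nf <- n %/% 2 + 1
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    ph <- exp(-2i * pi * (k - 1) * seq(0, n - 1) / n)
    X <- sum(xw * ph)
    sc <- if (k == 1 || k == nf) 1 else 2
    out[k] <- sc * Mod(X)^2 / (fs * sum(w^2))
  }
  out
}
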