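#' Preprocess a continuous EEG recording
#'
#' Band-pass filters every channel (second-order Butterworth, 0.5-45 Hz,
#' applied forward and backward so the net phase response is zero), drops
#' excluded and bad channels, decimates to the target rate, and re-references
#' to the average of the remaining good scalp channels. The 45 Hz low-pass
#' edge is below the decimated Nyquist rate, so plain decimation does not
#' alias.
#'
#' @param rec an `eeg_recording`.
#' @param exclude channel labels to drop (e.g. neck/face ring).
#' @param band band-pass edges in Hz.
#' @param target_fs output sampling rate; must divide `fs_hz`.
#' @param min_good_channels quality gate: error when fewer good channels
#'   remain (the study montage keeps >100; synthetic montages pass a lower
#'   bound explicitly).
#' @param rereference one of `"average"` or `"none"`. Mastoids never enter
#'   the average reference.
#' @return a preprocessed `eeg_recording` at `target_fs`.
#' @export
preprocess_eeg <- function(rec, exclude = character(0),
                           band = c(0.5, 45), target_fs = 125,
                           min_good_channels = 100L,
                           rereference = c("average", "none")) {
  stopifnot(inherits(rec, "eeg_recording"))
  rereference <- match.arg(rereference)
  if (rec$fs_hz < 250)
    stop_localwake("preprocessing expects a recording sampled at >= 250 Hz",
                   "localwake_domain_error")
  drop <- union(exclude, rec$annotations$bad_channels)
  keep <- setdiff(rec$channel_labels, drop)
  scalp <- setdiff(keep, rec$annotations$mastoids)
  if (length(scalp) < min_good_channels)
    stop_localwake(sprintf("only %d good scalp channels (< %d)", length(scalp),
                           min_good_channels), "localwake_quality_error")
  dec <- rec$fs_hz / target_fs
  if (abs(dec - round(dec)) > 1e-9)
    stop_localwake("target_fs must divide the sampling rate", "localwake_domain_error")
  dec <- as.integer(round(dec))
  flt <- cached_filter(sprintf("bp-%g-%g-%g", band[1], band[2], rec$fs_hz),
                       function() signal::butter(2, band / (rec$fs_hz / 2), type = "pass"))
  pick <- seq(1, ncol(rec$data), by = dec)
  out <- matrix(0, nrow = length(keep), ncol = length(pick))
  rownames(out) <- keep
  for (ch in keep)
    out[ch, ] <- signal::filtfilt(flt, rec$data[ch, ])[pick]
  if (rereference == "average") {
    ref <- colMeans(out[scalp, , drop = FALSE])
    out <- sweep(out, 2, ref)
  }
  rec$data <- out
  rec$channel_labels <- keep
  rec$positions <- rec$positions[keep, , drop = FALSE]
  rec$fs_hz <- target_fs
  rec$duration_s <- length(pick) / target_fs
  rec$reference <- rereference
  rec
}

#' Cut retrieval spans into fixed-length analysis windows
#'
#' Each retrieval's span runs from its onset annotation to the next onset
#' (the session is contiguous); the last span ends at the earlier of the
#' recording end and the annotated retrieval end. Spans are cut into
#' contiguous non-overlapping windows of `win_s` seconds; a trailing
#' remainder shorter than `win_s` is discarded, as is any window overlapping
#' an artifact span.
#'
#' @param rec an `eeg_recording` (annotations carry the retrieval onsets).
#' @param series the matching `retrieval_series`.
#' @param win_s window length in seconds.
#' @return data.frame with `retrieval_index` and window start time `t0`.
#' @export
epoch_by_retrieval <- function(rec, series, win_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  onsets <- rec$annotations$retrieval_onsets
  if (length(onsets) != nrow(series))
    stop_localwake("annotations must contain one onset per retrieval",
                   "localwake_domain_error")
  ends <- c(onsets[-1], min(rec$duration_s,
                            onsets[length(onsets)] + series$duration_s[nrow(series)]))
  res <- vector("list", length(onsets))
  arts <- rec$annotations$artifact_spans
  for (i in seq_along(onsets)) {
    span <- ends[i] - onsets[i]
    k <- floor(span / win_s)
    if (k < 1) next
    t0 <- onsets[i] + (seq_len(k) - 1) * win_s
    if (!is.null(arts) && nrow(arts)) {
      bad <- vapply(t0, function(s)
        any(s < arts[, 2] & (s + win_s) > arts[, 1]), logical(1))
      t0 <- t0[!bad]
    }
    if (length(t0))
      res[[i]] <- data.frame(retrieval_index = series$index[i], t0 = t0)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(retrieval_index = integer(0), t0 = numeric(0))
  out
}

#' Welch power spectral density over a set of windows
#'
#' Averages Hamming-tapered one-sided periodograms over non-overlapping
#' windows. With 4 s windows at 125 Hz the bins sit at 0, 0.25, ..., 62.5 Hz.
#' Density normalization is one-sided with taper power correction, so that
#' summing the density times the bin width recovers the signal variance
#' (Parseval).
#'
#' @param rec an `eeg_recording`.
#' @param windows data.frame from [epoch_by_retrieval()] (column `t0`), or a
#'   numeric vector of window start times.
#' @param win_s window length in seconds.
#' @param channels channel labels (default: all non-mastoid channels).
#' @return list of class `psd_estimate`: `freq` (Hz), `power` (channels x
#'   bins, uV^2/Hz), `n_windows`, `fs_hz`.
#' @export
welch_psd <- function(rec, windows, win_s = 4, channels = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  t0 <- if (is.data.frame(windows)) windows$t0 else as.numeric(windows)
  if (length(t0) == 0)
    stop_localwake("no analysis windows supplied", "localwake_insufficient_data")
  fs <- rec$fs_hz
  nw <- as.integer(round(win_s * fs))
  channels <- channels %||% setdiff(rec$channel_labels, rec$annotations$mastoids)
  w <- hamming_window(nw)
  u <- sum(w^2)                      # taper power correction
  nf <- nw %/% 2 + 1L
  freq <- (seq_len(nf) - 1) * fs / nw
  scale <- rep(2 / (fs * u), nf)
  scale[c(1L, nf)] <- 1 / (fs * u)   # DC and Nyquist are not doubled
  starts <- as.integer(round(t0 * fs)) + 1L
  bad <- starts < 1 | (starts + nw - 1L) > ncol(rec$data)
  starts <- starts[!bad]
  if (length(starts) == 0)
    stop_localwake("all windows fall outside the recording", "localwake_insufficient_data")
  power <- matrix(0, nrow = length(channels), ncol = nf,
                  dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    x <- rec$data[channels[ci], ]
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[s:(s + nw - 1L)] * w
      sp <- fft(seg)[seq_len(nf)]
      acc <- acc + (Re(sp)^2 + Im(sp)^2) * scale
    }
    power[ci, ] <- acc / length(starts)
  }
  structure(list(freq = freq, power = power, n_windows = length(starts),
                 fs_hz = fs, win_s = win_s),
            class = "psd_estimate")
}

#' Log-transformed mean band power
#'
#' Averages the PSD over all frequency bins inside the band (inclusive
#' endpoints) and applies log10. The log is taken after averaging.
#'
#' @param psd a `psd_estimate`.
#' @param band numeric length 2, band edges in Hz.
#' @param eps floor applied to nonpositive means before the log.
#' @return named numeric vector: log10 mean band power per channel.
#' @export
band_power <- function(psd, band, eps = 1e-20) {
  stopifnot(inherits(psd, "psd_estimate"), length(band) == 2)
  if (band[1] > band[2] || band[2] > max(psd$freq))
    stop_localwake("band outside the spectral range", "localwake_domain_error")
  sel <- psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9
  m <- rowMeans(psd$power[, sel, drop = FALSE])
  if (any(m <= 0)) {
    warning("nonpositive mean band power floored at eps")
    m <- pmax(m, eps)
  }
  log10(m)
}

#' Canonical frequency bands
#'
#' Delta is 1-4 Hz. The theta band defaults to 4.25-7.5 Hz; an alternative
#' 4.5-7.5 Hz definition is selectable.
#'
#' @param theta_lo lower theta edge (4.25 or 4.5).
#' @return named list of band edges.
#' @export
spectral_bands <- function(theta_lo = 4.25) {
  list(delta = c(1, 4), theta = c(theta_lo, 7.5))
}

#' Condition-wise band power
#'
#' Pools analysis windows per condition before Welch averaging and returns
#' log band power per channel, condition and band. Conditions are either the
#' label-by-interval cells of the wayfinding analysis (errors/hits in each
#' temporal interval) or plain intervals (`by_label = FALSE`, the
#' task-versus-control quartile analysis), plus a baseline condition built
#' from the first `n_baseline` retrievals or, when `baseline_clock` is given,
#' from all windows inside that clock interval (matched-baseline control).
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param series the `retrieval_series`.
#' @param labels a `labeled_series` (needed when `by_label = TRUE`).
#' @param partition an `interval_partition`.
#' @param bands named list of band edges, as [spectral_bands()].
#' @param by_label cross error/hit labels with intervals?
#' @param n_baseline retrievals forming the baseline estimate.
#' @param baseline_clock optional length-2 clock interval (s) for the
#'   baseline windows.
#' @param win_s window length (s).
#' @return data.frame: `channel`, `condition`, `band`, `log_power`,
#'   `n_windows`.
#' @export
condition_band_power <- function(rec, series, labels = NULL, partition,
                                 bands = spectral_bands(),
                                 by_label = TRUE, n_baseline = 16L,
                                 baseline_clock = NULL, win_s = 4) {
  wins <- epoch_by_retrieval(rec, series, win_s = win_s)
  if (nrow(wins) == 0)
    stop_localwake("no analysis windows in recording", "localwake_insufficient_data")
  interval <- partition$assignment[match(wins$retrieval_index, series$index)]
  cond <- rep(NA_character_, nrow(wins))
  if (by_label) {
    stopifnot(inherits(labels, "labeled_series"))
    lab <- labels$labels[match(wins$retrieval_index, series$index)]
    lab[lab == "best_hit"] <- "hit"
    sel <- lab %in% c("hit", "error") & !is.na(interval)
    cond[sel] <- paste0(ifelse(lab[sel] == "error", "errors_", "hits_"), interval[sel])
  } else {
    sel <- !is.na(interval)
    cond[sel] <- paste0("interval_", interval[sel])
  }
  if (is.null(baseline_clock)) {
    base_sel <- wins$retrieval_index <= n_baseline
  } else {
    base_sel <- wins$t0 >= baseline_clock[1] & (wins$t0 + win_s) <= baseline_clock[2]
  }
  cond[base_sel] <- "baseline"
  out <- list()
  for (cc in sort(unique(cond[!is.na(cond)]))) {
    t0 <- wins$t0[!is.na(cond) & cond == cc]
    if (length(t0) == 0) { message("condition ", cc, " has no windows; dropped"); next }
    psd <- welch_psd(rec, t0, win_s = win_s)
    for (bn in names(bands)) {
      bp <- band_power(psd, bands[[bn]])
      out[[paste(cc, bn)]] <- data.frame(channel = names(bp), condition = cc,
                                         band = bn, log_power = unname(bp),
                                         n_windows = psd$n_windows,
                                         stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
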