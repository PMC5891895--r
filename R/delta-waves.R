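#' Re-reference a recording to the average of the two mastoids
#'
#' Subtracts the mean of the mastoid channels from every channel and drops
#' the mastoids from the data (they carry no signal of their own afterwards
#' and are excluded from wave detection).
#'
#' @param rec an `eeg_recording` whose annotations name both mastoids.
#' @return the re-referenced `eeg_recording`.
#' @export
rereference_mastoids <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  mast <- rec$annotations$mastoids
  if (length(mast) != 2 || !all(mast %in% rec$channel_labels))
    stop_localwake("both mastoid channels must be present", "localwake_config_error")
  ref <- colMeans(rec$data[mast, , drop = FALSE])
  keep <- setdiff(rec$channel_labels, mast)
  rec$data <- sweep(rec$data[keep, , drop = FALSE], 2, ref)
  rec$channel_labels <- keep
  rec$positions <- rec$positions[keep, , drop = FALSE]
  rec$reference <- "mastoids"
  rec
}

#' Zero-phase 4 Hz Chebyshev type-II low-pass
#'
#' Sixth-order Chebyshev type-II design (stopband edge 8 Hz, 40 dB
#' attenuation by default), applied forward and backward so the net phase
#' distortion cancels and wave morphology is preserved. The design is
#' checked once per sampling rate: passband ripple below 4 Hz must stay
#' within 0.5 dB, otherwise an error reports the offending parameters.
#'
#' @param x numeric signal (or an `eeg_recording`, filtered per channel).
#' @param fs sampling rate (Hz, >= 100); taken from the recording if given.
#' @param stopband_hz stopband edge.
#' @param atten_db stopband attenuation in dB.
#' @param order filter order.
#' @return filtered signal of the same shape.
#' @export
lowpass_4hz <- function(x, fs = NULL, stopband_hz = 8, atten_db = 40, order = 6) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs_hz
    for (ch in x$channel_labels)
      x$data[ch, ] <- lowpass_4hz(x$data[ch, ], fs, stopband_hz, atten_db, order)
    return(x)
  }
  stopifnot(is.numeric(x))
  if (is.null(fs) || fs < 100)
    stop_localwake("fs must be supplied and >= 100 Hz", "localwake_domain_error")
  key <- sprintf("cheby2-%g-%g-%g-%g", order, atten_db, stopband_hz, fs)
  flt <- cached_filter(key, function() {
    f <- signal::cheby2(order, atten_db, stopband_hz / (fs / 2), type = "low")
    h <- signal::freqz(f, n = 2048, Fs = fs)
    pass <- abs(h$h[h$f >= 0.25 & h$f <= 4])
    ripple_db <- -20 * log10(min(pass))
    if (!is.finite(ripple_db) || ripple_db > 0.5)
      stop_localwake(sprintf(
        "unstable low-pass design (order %g, %g dB, stop %g Hz at fs %g): passband ripple %.2f dB",
        order, atten_db, stopband_hz, fs, ripple_db), "localwake_design_error")
    f
  })
  as.numeric(signal::filtfilt(flt, x))
}

# Detect negative half-waves in one filtered channel. Zero crossings are
# located by linear interpolation between samples; a sample exactly at zero
# belongs to the following segment (treated as nonnegative).
detect_half_waves_channel <- function(x, fs) {
  neg <- x < 0
  if (!any(neg)) return(NULL)
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_s <- starts[r$values]
  seg_e <- ends[r$values]
  # drop segments touching the recording edges (no bounding zero crossing)
  inside <- seg_s > 1L & seg_e < length(x)
  seg_s <- seg_s[inside]; seg_e <- seg_e[inside]
  if (length(seg_s) == 0) return(NULL)
  interp_down <- (seg_s - 1L) + x[seg_s - 1L] / (x[seg_s - 1L] - x[seg_s])
  interp_up <- seg_e + x[seg_e] / (x[seg_e] - x[seg_e + 1L])
  t_down <- (interp_down - 1) / fs
  t_up <- (interp_up - 1) / fs
  duration <- t_up - t_down
  keep <- duration >= 0.125 & duration <= 0.5
  if (!any(keep)) return(NULL)
  seg_s <- seg_s[keep]; seg_e <- seg_e[keep]
  t_down <- t_down[keep]; t_up <- t_up[keep]; duration <- duration[keep]
  pk <- mapply(function(a, b) { i <- a:b; i[which.min(x[i])] }, seg_s, seg_e)
  data.frame(t_zero_down = t_down, t_peak = (pk - 1) / fs, t_zero_up = t_up,
             amp_peak = x[pk], duration_s = duration)
}

#' Detect individual negative half-waves
#'
#' A half-wave is a negative deflection between two consecutive zero
#' crossings of the low-pass-filtered signal. Events whose crossing-to-
#' crossing duration falls outside 0.125-0.5 s (the half-wave duration range
#' of 1-4 Hz full waves) are discarded. Each event is assigned to the
#' retrieval containing its negative peak; events whose peak lies outside
#' every span, or inside an artifact span, are dropped.
#'
#' @param rec an `eeg_recording` already filtered with [lowpass_4hz()] (or a
#'   numeric vector together with `fs`).
#' @param fs sampling rate when `rec` is a plain vector.
#' @param spans data.frame with `retrieval_index`, `start`, `end` (s);
#'   defaults to spans built from the recording annotations.
#' @param artifacts optional matrix/data.frame of artifact spans (start, end).
#' @return data.frame of class `half_wave_events`: `channel`, `t_zero_down`,
#'   `t_peak`, `t_zero_up`, `amp_peak` (< 0), `duration_s`,
#'   `retrieval_index`.
#' @export
detect_half_waves <- function(rec, fs = NULL, spans = NULL, artifacts = NULL) {
  if (is.numeric(rec)) {
    stopifnot(!is.null(fs))
    ev <- detect_half_waves_channel(rec, fs)
    if (is.null(ev)) ev <- empty_half_waves()
    else ev <- cbind(channel = "x", ev, retrieval_index = NA_integer_)
    return(assign_spans(ev, spans, artifacts))
  }
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(spans) && !is.null(rec$annotations$retrieval_onsets)) {
    on <- rec$annotations$retrieval_onsets
    spans <- data.frame(retrieval_index = rec$annotations$retrieval_index %||% seq_along(on),
                        start = on, end = c(on[-1], rec$duration_s))
  }
  artifacts <- artifacts %||% rec$annotations$artifact_spans
  out <- lapply(rec$channel_labels, function(ch) {
    ev <- detect_half_waves_channel(rec$data[ch, ], rec$fs_hz)
    if (is.null(ev)) return(NULL)
    cbind(channel = ch, ev, retrieval_index = NA_integer_)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- empty_half_waves()
  assign_spans(out, spans, artifacts)
}

empty_half_waves <- function() {
  structure(data.frame(channel = character(0), t_zero_down = numeric(0),
                       t_peak = numeric(0), t_zero_up = numeric(0),
                       amp_peak = numeric(0), duration_s = numeric(0),
                       retrieval_index = integer(0)),
            class = c("half_wave_events", "data.frame"))
}

assign_spans <- function(ev, spans, artifacts) {
  if (nrow(ev) && !is.null(artifacts) && NROW(artifacts)) {
    arts <- as.matrix(artifacts)
    bad <- vapply(ev$t_peak, function(p) any(p >= arts[, 1] & p <= arts[, 2]),
                  logical(1))
    ev <- ev[!bad, , drop = FALSE]
  }
  if (nrow(ev) && !is.null(spans)) {
    idx <- findInterval(ev$t_peak, spans$start)
    inside <- idx >= 1 & idx <= nrow(spans) & ev$t_peak < spans$end[pmax(idx, 1)]
    ev <- ev[inside, , drop = FALSE]
    ev$retrieval_index <- spans$retrieval_index[idx[inside]]
  }
  class(ev) <- c("half_wave_events", "data.frame")
  rownames(ev) <- NULL
  ev
}

#' Retain the top-20 % amplitude half-waves (delta waves)
#'
#' Pools all detections of a subject per channel across the whole task,
#' weighting each event by the reciprocal of its retrieval's duration
#' (standardizing for retrieval length), and computes the weighted 80th
#' percentile of the negative peak magnitudes with linear interpolation.
#' Events whose magnitude strictly exceeds the threshold are the delta waves
#' kept for analysis. Channels with fewer than `min_events` detections are
#' skipped with a warning (their events get `retained = NA`).
#'
#' @param events a `half_wave_events` data.frame.
#' @param retrieval_durations named numeric: duration (s) per retrieval
#'   index, used for the reciprocal-duration weights.
#' @param prob percentile defining the threshold (0.8 = top 20 %).
#' @param weighting `"inverse_duration"` (default) or `"none"` (unweighted
#'   percentile).
#' @param min_events minimal detections per channel.
#' @return the events with columns `retained` (logical) and `threshold`
#'   (uV magnitude) appended.
#' @export
threshold_top20 <- function(events, retrieval_durations = NULL, prob = 0.8,
                            weighting = c("inverse_duration", "none"),
                            min_events = 5L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(events, "data.frame"))
  events$retained <- NA
  events$threshold <- NA_real_
  for (ch in unique(events$channel)) {
    sel <- events$channel == ch
    n <- sum(sel)
    if (n < min_events) {
      warning(sprintf("channel %s: only %d events (< %d); skipped", ch, n, min_events))
      next
    }
    a <- abs(events$amp_peak[sel])
    w <- if (weighting == "inverse_duration" && !is.null(retrieval_durations)) {
      d <- retrieval_durations[as.character(events$retrieval_index[sel])]
      if (any(is.na(d) | d <= 0))
        stop_localwake("missing or nonpositive retrieval duration for weighting",
                       "localwake_domain_error")
      1 / d
    } else 1
    thr <- weighted_quantile(a, w, prob)
    events$retained[sel] <- a > thr
    events$threshold[sel] <- thr
  }
  events
}

#' Summarize delta waves by scalp region and behavioral condition
#'
#' For each region (a disjoint electrode set) and condition (the behavioral
#' label of the owning retrieval, optionally crossed with a temporal
#' interval) reports the standardized wave count — events per minute of
#' condition time, averaged over the region's electrodes — and the mean
#' negative peak amplitude.
#'
#' @param events thresholded `half_wave_events` (only `retained` events are
#'   counted; pass `use_retained = FALSE` to summarize all detections).
#' @param regions named list of electrode label sets (disjoint).
#' @param series the `retrieval_series` (condition durations).
#' @param labels a `labeled_series`.
#' @param partition optional `interval_partition` to cross labels with
#'   intervals.
#' @param use_retained count only threshold-retained events?
#' @return data.frame: `region`, `condition`, `n_waves_per_min`,
#'   `mean_amp`, `n_events`, `minutes`.
#' @export
summarize_by_region <- function(events, regions, series, labels,
                                partition = NULL, use_retained = TRUE) {
  stopifnot(inherits(labels, "labeled_series"))
  if (anyDuplicated(unlist(regions)))
    stop_localwake("regions must be disjoint electrode sets", "localwake_config_error")
  ev <- events
  if (use_retained && "retained" %in% names(ev)) ev <- ev[!is.na(ev$retained) & ev$retained, ]
  lab <- labels$labels[match(ev$retrieval_index, series$index)]
  lab[lab == "best_hit"] <- "hit"
  cond_of <- labels$labels
  cond_of[cond_of == "best_hit"] <- "hit"
  if (!is.null(partition)) {
    iv <- partition$assignment[match(ev$retrieval_index, series$index)]
    lab <- ifelse(is.na(iv), NA, paste0(lab, "_", iv))
    cond_of <- ifelse(is.na(partition$assignment), NA,
                      paste0(cond_of, "_", partition$assignment))
  }
  out <- list()
  for (rg in names(regions)) {
    chans <- regions[[rg]]
    for (cc in c("hit", "error")) {
      conds <- if (is.null(partition)) cc else grep(paste0("^", cc, "_"), unique(cond_of), value = TRUE)
      for (cond in conds) {
        minutes <- sum(series$duration_s[!is.na(cond_of) & cond_of == cond]) / 60
        if (minutes <= 0) next
        sel <- !is.na(lab) & lab == cond & ev$channel %in% chans
        rate <- mean(vapply(chans, function(ch)
          sum(sel & ev$channel == ch) / minutes, numeric(1)))
        out[[paste(rg, cond)]] <- data.frame(
          region = rg, condition = cond,
          n_waves_per_min = rate,
          mean_amp = if (any(sel)) mean(ev$amp_peak[sel]) else NA_real_,
          n_events = sum(sel), minutes = minutes,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
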