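#' Synthetic EEG montage
#'
#' Builds channel positions on a unit upper hemisphere (x right, y anterior,
#' z up). For `n_channels = 8` a named 10-20-like subset is used (F3, F4, C3,
#' C4, P3, P4, O1, O2); larger montages are laid out on a Fibonacci spiral
#' over the upper hemisphere with labels `E1..En`. Two mastoid channels (M1,
#' M2) are always appended below the left/right ears.
#'
#' @param n_channels number of scalp channels (mastoids excluded).
#' @return list with `labels`, `positions` (matrix n x 3, row-named),
#'   `mastoids` (labels), and `regions` (named list of scalp electrode sets
#'   covering left parietal, left frontal, right frontal scalp).
#' @export
default_montage <- function(n_channels = 8L) {
  if (n_channels == 8L) {
    labels <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
    pos <- rbind(
      c(-0.45, 0.55, 0.70), c(0.45, 0.55, 0.70),
      c(-0.71, 0.00, 0.70), c(0.71, 0.00, 0.70),
      c(-0.45, -0.55, 0.70), c(0.45, -0.55, 0.70),
      c(-0.31, -0.95, 0.10), c(0.31, -0.95, 0.10)
    )
  } else {
    i <- seq_len(n_channels)
    golden <- pi * (3 - sqrt(5))
    z <- (i - 0.5) / n_channels          # height on upper hemisphere
    r <- sqrt(1 - z^2)
    pos <- cbind(r * cos(golden * i), r * sin(golden * i), z)
    labels <- paste0("E", i)
  }
  rownames(pos) <- labels
  mast_pos <- rbind(M1 = c(-0.95, -0.25, -0.35), M2 = c(0.95, -0.25, -0.35))
  positions <- rbind(pos, mast_pos)
  regions <- list(
    left_frontal  = labels[pos[, 1] < -0.1 & pos[, 2] > 0.25],
    right_frontal = labels[pos[, 1] > 0.1 & pos[, 2] > 0.25],
    left_parietal = labels[pos[, 1] < -0.1 & pos[, 2] < -0.25]
  )
  list(labels = labels, positions = positions, mastoids = c("M1", "M2"),
       regions = regions)
}

#' Configuration for the synthetic EEG generator
#'
#' The background emulates task-engaged waking EEG: a pink (`1/f^slope`)
#' broadband component with low delta-band power, a prominent alpha rhythm and
#' an ongoing theta rhythm whose amplitude rises in the last quartile of the
#' session (end-of-task sleepiness marker). Individual delta half-waves
#' (negative half-sine deflections, duration uniform on 0.125-0.5 s) are
#' injected at condition-dependent Poisson rates that drift upward with
#' time-on-task and are elevated, with larger negative peaks, during error
#' retrievals. Amplitudes are in microvolts.
#'
#' @param n_channels scalp channels.
#' @param fs_hz sampling rate (Hz).
#' @param background_slope spectral exponent of the broadband background.
#' @param background_rms RMS amplitude of the broadband background (uV).
#' @param alpha_amp,alpha_freq alpha oscillation amplitude (uV) and frequency.
#' @param theta_amp,theta_freq theta oscillation amplitude (uV) and frequency.
#' @param theta_boost_last_quartile multiplicative theta amplitude factor in
#'   the final quarter of the session.
#' @param delta_wave_rate_hit,delta_wave_rate_error injected half-wave rates
#'   (events/min) during non-error and error retrievals.
#' @param delta_amp_mean_hit,delta_amp_mean_error mean negative peak
#'   amplitudes (uV, negative) by condition.
#' @param delta_amp_sd sd of injected peak amplitudes (uV).
#' @param rate_drift_per_min increase of the injection rate (events/min) per
#'   minute of time-on-task.
#' @param max_overlap_frac warn when more than this fraction of drawn events
#'   is discarded by overlap thinning.
#' @param mastoid_gain background amplitude factor for the mastoid channels.
#' @param montage as from [default_montage()].
#' @param pad_s seconds of recording appended after the last retrieval.
#' @param seed integer seed.
#' @return list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(n_channels = 8L,
                           fs_hz = 250,
                           background_slope = 1.5,
                           background_rms = 3,
                           alpha_amp = 15, alpha_freq = 10,
                           theta_amp = 12, theta_freq = 6,
                           theta_boost_last_quartile = 2,
                           delta_wave_rate_hit = 3,
                           delta_wave_rate_error = 9,
                           delta_amp_mean_hit = -40,
                           delta_amp_mean_error = -55,
                           delta_amp_sd = 5,
                           rate_drift_per_min = 0.04,
                           max_overlap_frac = 0.2,
                           mastoid_gain = 0.2,
                           montage = default_montage(n_channels),
                           pad_s = 2,
                           seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$delta_wave_rate_error < cfg$delta_wave_rate_hit)
    stop_localwake("delta_wave_rate_error must be >= delta_wave_rate_hit",
                   "localwake_invalid_config")
  if (abs(cfg$delta_amp_mean_error) < abs(cfg$delta_amp_mean_hit))
    stop_localwake("|delta_amp_mean_error| must be >= |delta_amp_mean_hit|",
                   "localwake_invalid_config")
  if (any(c(cfg$delta_amp_mean_hit, cfg$delta_amp_mean_error) >= 0))
    stop_localwake("injected wave amplitudes must be negative",
                   "localwake_invalid_config")
  if (cfg$fs_hz <= 2 * max(cfg$alpha_freq, cfg$theta_freq, 4))
    stop_localwake("fs_hz must exceed twice the highest synthesized frequency",
                   "localwake_invalid_config")
  class(cfg) <- "eeg_sim_config"
  cfg
}

#' Signal-to-noise ratio implied by an injection amplitude
#'
#' SNR is defined as the absolute injected peak amplitude divided by the RMS
#' of the broadband background (pink noise plus alpha and theta rhythms);
#' `snr_to_amp` returns the (negative) amplitude realizing a target SNR.
#'
#' @param config an [eeg_sim_config()].
#' @param snr target signal-to-noise ratio.
#' @return negative amplitude in uV.
#' @export
snr_to_amp <- function(config, snr) {
  stopifnot(inherits(config, "eeg_sim_config"), snr > 0)
  -snr * sqrt(config$background_rms^2 + config$alpha_amp^2 / 2 +
                config$theta_amp^2 / 2)
}

#' Generate a synthetic EEG recording aligned to a retrieval series
#'
#' @param config an [eeg_sim_config()].
#' @param behavior retrieval series from [gen_behavior()].
#' @param truth ground-truth list from [gen_behavior()]; per-retrieval labels
#'   select the condition-dependent injection rate and amplitude.
#' @return list with `recording` (class `eeg_recording`: `channel_labels`,
#'   `positions`, `fs_hz`, `data` channels x samples, `annotations`) and
#'   `truth` (the input truth extended with `injected_events`, a data.frame
#'   of channel, onset, peak time, amplitude, duration, retrieval index).
#' @export
gen_eeg <- function(config, behavior, truth) {
  stopifnot(inherits(config, "eeg_sim_config"))
  if (nrow(behavior) == 0)
    stop_localwake("behavior series is empty", "localwake_invalid_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs_hz
  session_end <- behavior$start_time_s[nrow(behavior)] +
    behavior$duration_s[nrow(behavior)]
  n <- ceiling((session_end + config$pad_s) * fs)
  tt <- (seq_len(n) - 1) / fs
  labels <- config$montage$labels
  n_scalp <- length(labels)
  theta_env <- 1 + (config$theta_boost_last_quartile - 1) * (tt >= 0.75 * session_end)

  data <- matrix(0, nrow = n_scalp + 2L, ncol = n)
  rownames(data) <- c(labels, config$montage$mastoids)
  for (ch in seq_len(n_scalp)) {
    data[ch, ] <- config$background_rms * one_over_f_noise(n, fs, config$background_slope) +
      config$alpha_amp * sin(2 * pi * config$alpha_freq * tt + runif(1, 0, 2 * pi)) +
      config$theta_amp * theta_env * sin(2 * pi * config$theta_freq * tt + runif(1, 0, 2 * pi))
  }
  for (m in 1:2) {
    data[n_scalp + m, ] <- config$mastoid_gain * config$background_rms *
      one_over_f_noise(n, fs, config$background_slope)
  }

  # condition-dependent Poisson injection of negative half-sine waves
  lab <- truth$true_labels
  rate0 <- ifelse(lab == "error", config$delta_wave_rate_error,
                  config$delta_wave_rate_hit)
  amp_mu <- ifelse(lab == "error", config$delta_amp_mean_error,
                   config$delta_amp_mean_hit)
  events <- vector("list", n_scalp)
  n_drawn <- 0L
  n_kept <- 0L
  for (ch in seq_len(n_scalp)) {
    ev_on <- numeric(0); ev_du <- numeric(0); ev_am <- numeric(0); ev_ri <- integer(0)
    for (i in seq_len(nrow(behavior))) {
      t0 <- behavior$start_time_s[i]
      dur <- behavior$duration_s[i]
      rate <- max(0, rate0[i] + config$rate_drift_per_min * t0 / 60)
      k <- rpois(1, rate * dur / 60)
      if (k == 0) next
      du <- runif(k, 0.125, 0.5)
      on <- t0 + runif(k, 0, pmax(0, dur - du))
      am <- -abs(rnorm(k, mean = -amp_mu[i], sd = config$delta_amp_sd))
      ev_on <- c(ev_on, on); ev_du <- c(ev_du, du); ev_am <- c(ev_am, am)
      ev_ri <- c(ev_ri, rep(i, k))
    }
    n_drawn <- n_drawn + length(ev_on)
    if (length(ev_on)) {
      o <- order(ev_on)
      ev_on <- ev_on[o]; ev_du <- ev_du[o]; ev_am <- ev_am[o]; ev_ri <- ev_ri[o]
      keep <- rep(TRUE, length(ev_on))
      last_end <- -Inf; last_du <- 0
      for (j in seq_along(ev_on)) {
        overlap <- last_end - ev_on[j]
        if (overlap > 0.5 * min(last_du, ev_du[j])) {
          keep[j] <- FALSE
        } else {
          last_end <- ev_on[j] + ev_du[j]; last_du <- ev_du[j]
        }
      }
      ev_on <- ev_on[keep]; ev_du <- ev_du[keep]; ev_am <- ev_am[keep]; ev_ri <- ev_ri[keep]
    }
    n_kept <- n_kept + length(ev_on)
    for (j in seq_along(ev_on)) {
      i0 <- floor(ev_on[j] * fs)
      i1 <- min(n - 1L, floor((ev_on[j] + ev_du[j]) * fs))
      idx <- i0:i1
      tau <- (idx / fs - ev_on[j]) / ev_du[j]
      data[ch, idx + 1L] <- data[ch, idx + 1L] + ev_am[j] * sin(pi * pmin(pmax(tau, 0), 1))
    }
    events[[ch]] <- if (length(ev_on)) {
      data.frame(channel = labels[ch], onset_s = ev_on,
                 t_peak = ev_on + ev_du / 2, amp_peak = ev_am,
                 duration_s = ev_du, retrieval_index = ev_ri,
                 stringsAsFactors = FALSE)
    } else NULL
  }
  if (n_drawn > 0 && (n_drawn - n_kept) / n_drawn > config$max_overlap_frac)
    warning(sprintf("overlap thinning discarded %.1f%% of drawn events",
                    100 * (n_drawn - n_kept) / n_drawn))
  injected <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(injected))
    injected <- data.frame(channel = character(0), onset_s = numeric(0),
                           t_peak = numeric(0), amp_peak = numeric(0),
                           duration_s = numeric(0), retrieval_index = integer(0))

  recording <- structure(list(
    channel_labels = rownames(data),
    positions = config$montage$positions,
    fs_hz = fs,
    data = data,
    annotations = list(
      retrieval_onsets = behavior$start_time_s,
      retrieval_index = behavior$index,
      artifact_spans = NULL,
      bad_channels = character(0),
      mastoids = config$montage$mastoids
    ),
    duration_s = n / fs
  ), class = "eeg_recording")

  truth$injected_events <- injected
  truth$eeg_config <- config
  list(recording = recording, truth = truth)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$duration_s / 60))
  invisible(x)
}
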