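test_that("behavior generator is deterministic and honours degenerate settings", {
  cfg <- behavior_sim_config(seed = 7, n_retrievals = 60, true_breakpoint_index = 30)
  a <- gen_behavior(cfg)
  b <- gen_behavior(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$truth$true_labels, b$truth$true_labels)

  cfg0 <- behavior_sim_config(seed = 8, error_prob_first_half = 0,
                              error_prob_second_half = 0)
  z <- gen_behavior(cfg0)
  expect_length(z$truth$true_error_index, 0)
  expect_false(any(z$truth$true_labels == "error"))

  # contiguity: each retrieval starts when the previous one ends
  expect_equal(z$series$start_time_s[-1],
               cumsum(z$series$duration_s)[-nrow(z$series)], tolerance = 1e-9)
  expect_true(all(z$series$duration_s > 0))

  expect_error(behavior_sim_config(error_prob_first_half = 1.2),
               class = "localwake_invalid_config")
  expect_error(behavior_sim_config(n_retrievals = 4),
               class = "localwake_invalid_config")
  expect_error(behavior_sim_config(stable_duration_mean = -1),
               class = "localwake_invalid_config")
})

test_that("breakpoint is recoverable from generated sessions across seeds", {
  hits <- vapply(1:50, function(sd) {
    b <- gen_behavior(behavior_sim_config(seed = sd, n_retrievals = 300,
                                          true_breakpoint_index = 60))
    bp <- tryCatch(find_breakpoint(b$series)$chosen, error = function(e) NA_integer_)
    !is.na(bp) && abs(bp - 60) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("EEG generator injects template waves with correct bookkeeping", {
  b <- gen_behavior(behavior_sim_config(seed = 51, n_retrievals = 30,
                                        true_breakpoint_index = 20,
                                        baseline_duration_mean = 20,
                                        stable_duration_mean = 15))
  cfg <- eeg_sim_config(seed = 52)
  e1 <- gen_eeg(cfg, b$series, b$truth)
  e2 <- gen_eeg(cfg, b$series, b$truth)
  expect_identical(e1$recording$data, e2$recording$data)   # determinism
  inj <- e1$truth$injected_events
  expect_true(all(inj$onset_s >= 0))
  expect_true(all(inj$onset_s + inj$duration_s <= e1$recording$duration_s))
  expect_true(all(inj$amp_peak < 0))
  expect_true(all(inj$duration_s >= 0.125 & inj$duration_s <= 0.5))
  expect_length(e1$truth$true_labels, nrow(b$series))
  # events do not overlap by more than half their duration within a channel
  for (ch in unique(inj$channel)) {
    ei <- inj[inj$channel == ch, ]
    ei <- ei[order(ei$onset_s), ]
    if (nrow(ei) > 1) {
      ov <- head(ei$onset_s + ei$duration_s, -1) - ei$onset_s[-1]
      lim <- 0.5 * pmin(head(ei$duration_s, -1), ei$duration_s[-1])
      expect_true(all(ov <= lim + 1e-9))
    }
  }
  expect_error(eeg_sim_config(delta_wave_rate_hit = 5, delta_wave_rate_error = 2),
               class = "localwake_invalid_config")
})

test_that("a single injected wave on a quiet background is recovered within one sample", {
  b <- gen_behavior(behavior_sim_config(seed = 61, n_retrievals = 20,
                                        true_breakpoint_index = 18,
                                        baseline_duration_mean = 10,
                                        stable_duration_mean = 10,
                                        error_prob_first_half = 0,
                                        error_prob_second_half = 0,
                                        distraction_prob = 0))
  cfg <- eeg_sim_config(seed = 62, n_channels = 8, background_rms = 1e-3,
                        alpha_amp = 0, theta_amp = 1e-3,
                        delta_wave_rate_hit = 0, delta_wave_rate_error = 0,
                        rate_drift_per_min = 0)
  ee <- gen_eeg(cfg, b$series, b$truth)
  rec <- ee$recording
  # inject one wave by hand at a known time on one channel
  fs <- rec$fs_hz
  t0 <- 50; dur <- 0.3; amp <- -40
  idx <- floor(t0 * fs):floor((t0 + dur) * fs)
  tau <- (idx / fs - t0) / dur
  rec$data["F3", idx + 1] <- rec$data["F3", idx + 1] + amp * sin(pi * tau)
  prep <- preprocess_eeg(rec, min_good_channels = 2L)
  wrec <- lowpass_4hz(rereference_mastoids(prep))
  ev <- detect_half_waves(wrec)
  # the detector has no amplitude floor, so the near-zero background still
  # yields micro-deflections; the injected wave is the only sizeable event
  ev <- ev[ev$channel == "F3" & ev$amp_peak < -20, ]
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$t_peak - (t0 + dur / 2)), 1 / prep$fs_hz + 1e-9)
})

test_that("zero injection rate leaves only a small noise-floor event rate", {
  b <- gen_behavior(behavior_sim_config(seed = 71, n_retrievals = 30,
                                        true_breakpoint_index = 20,
                                        baseline_duration_mean = 20,
                                        stable_duration_mean = 20))
  cfg <- eeg_sim_config(seed = 72, delta_wave_rate_hit = 0,
                        delta_wave_rate_error = 0, rate_drift_per_min = 0)
  ee <- gen_eeg(cfg, b$series, b$truth)
  prep <- preprocess_eeg(ee$recording, min_good_channels = 2L)
  ev <- detect_half_waves(lowpass_4hz(rereference_mastoids(prep)))
  minutes <- ee$recording$duration_s / 60
  fp_rate <- nrow(ev) / (8 * minutes)    # events per channel-minute
  expect_lt(fp_rate, 1)
})

test_that("error/hit injection rate ratio propagates to detected counts", {
  b <- gen_behavior(behavior_sim_config(seed = 81, n_retrievals = 100,
                                        true_breakpoint_index = 25,
                                        baseline_duration_mean = 18,
                                        stable_duration_mean = 15,
                                        error_prob_first_half = 0.4,
                                        error_prob_second_half = 0.4,
                                        distraction_prob = 0))
  cfg <- eeg_sim_config(seed = 82, rate_drift_per_min = 0,
                        delta_wave_rate_hit = 3, delta_wave_rate_error = 9,
                        delta_amp_mean_error = -55)
  ee <- gen_eeg(cfg, b$series, b$truth)
  prep <- preprocess_eeg(ee$recording, min_good_channels = 2L)
  ev <- detect_half_waves(lowpass_4hz(rereference_mastoids(prep)))
  lab <- ee$truth$true_labels[ev$retrieval_index]
  t_err <- sum(b$series$duration_s[ee$truth$true_labels == "error"])
  t_hit <- sum(b$series$duration_s[ee$truth$true_labels %in% c("hit", "baseline", "pre_stable")])
  rate_err <- sum(lab == "error") / t_err
  rate_hit <- sum(lab != "error") / t_hit
  expect_gt(rate_err / rate_hit, 2.2)
  expect_lt(rate_err / rate_hit, 3.8)
})

test_that("path-model generator matches its population moments", {
  d0 <- gen_path_data(c(0, 0, 0), n = 20000, seed = 5)
  cc <- cor(d0)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)

  b <- c(0.67, 0.48, 0.45)
  d <- gen_path_data(b, n = 1e5, seed = 6)
  expect_equal(cor(d$improvement, d$saturation), 0.67, tolerance = 0.01)
  expect_equal(cor(d$saturation, d$local_sleep), 0.48, tolerance = 0.01)
  # product rule along the recursive chain
  expect_equal(cor(d$improvement, d$local_sleep), 0.67 * 0.48, tolerance = 0.015)
  # variance calibration
  expect_true(all(abs(apply(d, 2, var) - 1) < 0.02))
  # determinism
  expect_identical(gen_path_data(b, 100, seed = 9), gen_path_data(b, 100, seed = 9))

  expect_error(gen_path_data(c(1.2, 0, 0), 100), class = "localwake_invalid_config")
  expect_error(gen_path_data(b, 5), class = "localwake_invalid_config")
})
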