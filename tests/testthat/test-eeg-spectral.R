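test_that("preprocessing removes DC, preserves passband tones and centers the average", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  x <- rbind(c1 = 5 + 0 * t,                       # DC only
             c2 = sin(2 * pi * 10 * t),            # passband tone
             c3 = sin(2 * pi * 20 * t),
             c4 = rnorm(length(t)))
  rec <- make_recording(x, fs)
  prep <- preprocess_eeg(rec, min_good_channels = 2L, rereference = "none")
  expect_equal(prep$fs_hz, 125)
  mid <- 500:1500                                   # avoid filter edge effects
  expect_lt(max(abs(prep$data["c1", mid])), 0.05)   # DC removed
  amp10 <- max(abs(prep$data["c2", mid]))
  expect_gt(amp10, 0.95); expect_lt(amp10, 1.05)
  amp20 <- max(abs(prep$data["c3", mid]))           # decimation preserves sub-45 Hz
  expect_gt(amp20, 0.95); expect_lt(amp20, 1.02)

  prep2 <- preprocess_eeg(rec, min_good_channels = 2L)
  expect_lt(max(abs(colMeans(prep2$data))), 1e-10)  # common-average identity

  expect_error(preprocess_eeg(rec, min_good_channels = 100L),
               class = "localwake_quality_error")
})

test_that("epoching floors retrieval spans into 4 s windows inside retrieval bounds", {
  fs <- 125
  durs <- c(10, 3.9, 8.5, 12)
  s <- make_series(durs)
  x <- matrix(rnorm(fs * 40), nrow = 1)
  rec <- make_recording(x, fs, onsets = s$start_time_s, retrieval_index = s$index)
  w <- epoch_by_retrieval(rec, s)
  expect_equal(sum(w$retrieval_index == 1), 2)      # floor(10/4)
  expect_equal(sum(w$retrieval_index == 2), 0)      # shorter than a window
  expect_equal(sum(w$retrieval_index == 3), 2)
  # windows never cross retrieval boundaries
  ends <- cumsum(durs)
  starts <- c(0, head(ends, -1))
  for (i in seq_len(nrow(w))) {
    ri <- w$retrieval_index[i]
    expect_gte(w$t0[i], starts[ri])
    expect_lte(w$t0[i] + 4, ends[ri] + 1e-9)
  }
})

test_that("Welch PSD satisfies Parseval and matches a direct DFT oracle", {
  fs <- 125
  t <- (0:(fs * 40 - 1)) / fs
  rec <- make_recording(sin(2 * pi * 2 * t), fs)
  p <- welch_psd(rec, seq(0, 36, by = 4))
  expect_equal(p$freq[2] - p$freq[1], 0.25)
  expect_equal(sum(p$power) * 0.25, 0.5, tolerance = 0.01)   # unit sine: var 1/2
  expect_equal(p$freq[which.max(p$power)], 2)

  set.seed(31)
  xn <- rnorm(fs * 400, sd = 1.5)
  pn <- welch_psd(make_recording(xn, fs), seq(0, 396, by = 4))
  expect_equal(sum(pn$power) * 0.25, 1.5^2, tolerance = 0.05 * 1.5^2)

  # oracle comparison on 3 windows
  x3 <- rnorm(fs * 12)
  p3 <- welch_psd(make_recording(x3, fs), c(0, 4, 8))
  oracle <- (oracle_periodogram(x3[1:500], fs) +
             oracle_periodogram(x3[501:1000], fs) +
             oracle_periodogram(x3[1001:1500], fs)) / 3
  expect_equal(as.numeric(p3$power[1, ]), oracle, tolerance = 1e-10)

  expect_error(welch_psd(rec, numeric(0)), class = "localwake_insufficient_data")
})

test_that("band power averages the right bins and logs after averaging", {
  psd <- structure(list(freq = seq(0, 62.5, by = 0.25),
                        power = matrix(2, nrow = 1, ncol = 251,
                                       dimnames = list("c1", NULL)),
                        n_windows = 1, fs_hz = 125, win_s = 4),
                   class = "psd_estimate")
  expect_equal(unname(band_power(psd, c(1, 4))), log10(2))
  # bin counts at 0.25 Hz spacing
  expect_equal(sum(psd$freq >= 1 - 1e-9 & psd$freq <= 4 + 1e-9), 13)
  expect_equal(sum(psd$freq >= 4.25 - 1e-9 & psd$freq <= 7.5 + 1e-9), 14)
  # disjoint delta/theta
  delta_bins <- which(psd$freq >= 1 - 1e-9 & psd$freq <= 4 + 1e-9)
  theta_bins <- which(psd$freq >= 4.25 - 1e-9 & psd$freq <= 7.5 + 1e-9)
  expect_length(intersect(delta_bins, theta_bins), 0)
  expect_error(band_power(psd, c(60, 70)), class = "localwake_domain_error")
})

test_that("welch estimates are invariant to channel order and window order", {
  fs <- 125
  set.seed(32)
  x <- matrix(rnorm(2 * fs * 20), nrow = 2, dimnames = list(c("a", "b"), NULL))
  rec <- make_recording(x, fs)
  rec_swapped <- make_recording(x[c("b", "a"), ], fs)
  p1 <- welch_psd(rec, c(0, 4, 8, 12))
  p2 <- welch_psd(rec_swapped, c(0, 4, 8, 12))
  expect_equal(p1$power["a", ], p2$power["a", ])
  p3 <- welch_psd(rec, c(12, 4, 0, 8))
  expect_equal(p1$power, p3$power)
})

test_that("condition-wise band power produces the expected bookkeeping", {
  set.seed(33)
  b <- gen_behavior(behavior_sim_config(seed = 34, n_retrievals = 40,
                                        true_breakpoint_index = 20,
                                        baseline_duration_mean = 12,
                                        stable_duration_mean = 10,
                                        error_prob_first_half = 0,
                                        error_prob_second_half = 0,
                                        distraction_prob = 0))
  ee <- gen_eeg(eeg_sim_config(seed = 35), b$series, b$truth)
  prep <- preprocess_eeg(ee$recording, min_good_channels = 2L)
  bp <- find_breakpoint(b$series)
  labels <- suppressWarnings(classify_retrievals(b$series, bp))
  part <- partition_intervals(b$series, bp, k = 2L)
  tab <- condition_band_power(prep, b$series, labels, part)
  # no errors: exactly baseline + hits_1 + hits_2
  expect_setequal(unique(tab$condition), c("baseline", "hits_1", "hits_2"))
  expect_setequal(unique(tab$band), c("delta", "theta"))
  expect_equal(sum(tab$condition == "baseline" & tab$band == "delta"), 8)
})
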