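test_that("mastoid re-referencing subtracts the mastoid mean exactly", {
  set.seed(41)
  x <- matrix(rnorm(5 * 1000), nrow = 5,
              dimnames = list(c("a", "b", "c", "M1", "M2"), NULL))
  rec <- make_recording(x, 125, mastoids = c("M1", "M2"))
  out <- rereference_mastoids(rec)
  ref <- colMeans(x[c("M1", "M2"), ])
  for (ch in c("a", "b", "c"))
    expect_equal(out$data[ch, ], x[ch, ] - ref, tolerance = 1e-12)
  expect_false(any(c("M1", "M2") %in% out$channel_labels))

  # zero mastoids leave signals unchanged; common offset is rejected
  x0 <- x; x0[c("M1", "M2"), ] <- 0
  out0 <- rereference_mastoids(make_recording(x0, 125, mastoids = c("M1", "M2")))
  expect_equal(out0$data["a", ], x0["a", ])
  xc <- x + 7
  outc <- rereference_mastoids(make_recording(xc, 125, mastoids = c("M1", "M2")))
  expect_equal(outc$data["a", ], x["a", ] - colMeans(x[c("M1", "M2"), ]),
               tolerance = 1e-12)

  rec_nom <- make_recording(x[1:3, ], 125)
  expect_error(rereference_mastoids(rec_nom), class = "localwake_config_error")
})

test_that("the 4 Hz low-pass keeps slow waves, kills fast ones, and has zero lag", {
  fs <- 125
  t <- (0:(fs * 30 - 1)) / fs
  mid <- 1000:2500
  y1 <- lowpass_4hz(sin(2 * pi * 1 * t), fs)
  expect_gte(max(abs(y1[mid])), 0.95)
  y20 <- lowpass_4hz(sin(2 * pi * 20 * t), fs)
  expect_lte(max(abs(y20[mid])), 0.01)
  # zero net phase: cross-correlation of input and output peaks at lag 0
  xin <- sin(2 * pi * 1 * t)
  cc <- stats::ccf(xin[mid], y1[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("half-wave detection is exact on an analytic sinusoid", {
  fs <- 125
  A <- 30
  # 10 s of oscillation with a short positive tail so the final half-wave is
  # bounded by zero crossings rather than the recording edge
  t <- seq(0, 10.3, by = 1 / fs)
  # negative half-waves of a 2 Hz sinusoid: 20 in 10 s, amplitude -A, 0.25 s
  ev2 <- detect_half_waves(A * sin(2 * pi * 2 * t), fs = fs)
  ev2 <- ev2[ev2$t_zero_up <= 10 + 1e-6, ]
  expect_equal(nrow(ev2), 20)
  expect_equal(ev2$amp_peak, rep(-A, 20), tolerance = 1e-2)
  expect_equal(ev2$duration_s, rep(0.25, 20), tolerance = 1e-3)
  expect_true(all(ev2$t_zero_down < ev2$t_peak & ev2$t_peak < ev2$t_zero_up))

  # 10 Hz sinusoid: all half-waves fail the duration gate
  ev10 <- detect_half_waves(sin(2 * pi * 10 * t), fs = fs)
  expect_equal(nrow(ev10), 0)

  # an all-positive signal yields an empty result, not an error
  ev_pos <- detect_half_waves(2 + sin(2 * pi * 2 * t), fs = fs)
  expect_equal(nrow(ev_pos), 0)
})

test_that("amplitude thresholding reproduces the weighted-percentile example", {
  ev <- data.frame(channel = "c1",
                   t_zero_down = seq_len(100), t_peak = seq_len(100) + 0.1,
                   t_zero_up = seq_len(100) + 0.2,
                   amp_peak = -(1:100), duration_s = 0.2,
                   retrieval_index = 1L)
  durs <- c("1" = 10)
  out <- threshold_top20(ev, durs)
  expect_equal(out$threshold[1], 80.2)
  expect_equal(sum(out$retained), 20)

  # equal amplitudes: nothing strictly exceeds the threshold
  ev_eq <- ev; ev_eq$amp_peak <- rep(-5, 100)
  expect_equal(sum(threshold_top20(ev_eq, durs)$retained), 0)

  # scale equivariance: doubling amplitudes doubles the threshold, same set
  ev2 <- ev; ev2$amp_peak <- 2 * ev$amp_peak
  out2 <- threshold_top20(ev2, durs)
  expect_equal(out2$threshold[1], 2 * out$threshold[1])
  expect_identical(out2$retained, out$retained)

  # retained count under equal weights and distinct amplitudes
  for (n in c(23, 40, 77)) {
    evn <- ev[1:n, ]
    kept <- sum(threshold_top20(evn, durs)$retained)
    expect_true(kept %in% c(floor(0.2 * n), ceiling(0.2 * n)))
  }

  # fewer than 5 events on a channel: skipped with a warning
  expect_warning(threshold_top20(ev[1:3, ], durs), "skipped")
})

test_that("region summaries standardize counts by condition minutes", {
  s <- make_series(rep(60, 20))                      # 20 x 1 min retrievals
  labels <- structure(list(labels = rep(c("hit", "error"), each = 10),
                           counts = table(rep(c("hit", "error"), each = 10)),
                           breakpoint = 1L), class = "labeled_series")
  # 10 events on one channel, all inside hit retrievals (first 10 minutes)
  ev <- data.frame(channel = "c1",
                   t_zero_down = seq(30, 570, length.out = 10),
                   t_peak = seq(30, 570, length.out = 10),
                   t_zero_up = seq(30, 570, length.out = 10) + 0.2,
                   amp_peak = -50, duration_s = 0.2,
                   retrieval_index = rep(1:10, each = 1),
                   retained = TRUE, threshold = 10)
  out <- summarize_by_region(ev, list(roi = "c1"), s, labels)
  expect_equal(out$n_waves_per_min[out$condition == "hit"], 1)   # 10 events / 10 min
  expect_equal(out$mean_amp[out$condition == "hit"], -50)

  # region average equals the mean of per-channel rates
  ev2 <- rbind(ev, within(ev, channel <- "c2")[1:4, ])
  out2 <- summarize_by_region(ev2, list(roi = c("c1", "c2")), s, labels)
  expect_equal(out2$n_waves_per_min[out2$condition == "hit"], (10 / 10 + 4 / 10) / 2)

  expect_error(summarize_by_region(ev, list(a = "c1", b = "c1"), s, labels),
               class = "localwake_config_error")
})
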