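test_that("optimal path length is the Euclidean distance and is symmetric", {
  expect_equal(optimal_path_length(c(0, 0), c(0, 0)), 0)
  expect_equal(optimal_path_length(c(0, 0), c(3, 4)), 5)
  set.seed(11)
  for (i in 1:100) {
    a <- runif(2, -50, 50); b <- runif(2, -50, 50); c <- runif(2, -50, 50)
    hyp <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)
    expect_equal(optimal_path_length(a, b), hyp, tolerance = 1e-12)
    expect_identical(optimal_path_length(a, b), optimal_path_length(b, a))
    # triangle inequality
    expect_lte(optimal_path_length(a, c),
               optimal_path_length(a, b) + optimal_path_length(b, c) + 1e-12)
  }
  expect_error(optimal_path_length(c(0, NA), c(1, 1)), class = "localwake_domain_error")
})

test_that("deviation from optimal matches hand-computed values and is order invariant", {
  perfect <- make_series(rep(10, 3), units = rep(5, 3))
  expect_equal(deviation_from_optimal(perfect), 0)
  twice <- make_series(rep(10, 2), units = rep(10, 2))   # units = 2 x optimal
  expect_equal(deviation_from_optimal(twice), -100)
  oneandhalf <- make_series(10, units = 7.5)
  expect_equal(deviation_from_optimal(oneandhalf), -50)
  set.seed(12)
  s <- make_series(rep(10, 20), units = 5 * (1 + runif(20)))
  shuffled <- s[sample(nrow(s)), ]
  expect_equal(deviation_from_optimal(s), deviation_from_optimal(shuffled))
  degen <- make_series(10, x2 = 0, z2 = 0, units = 1)
  expect_error(deviation_from_optimal(degen), class = "localwake_degenerate_route")
})

test_that("breakpoint detection recovers a step change and applies the farthest rule", {
  set.seed(21)
  dur <- c(rnorm(60, 10, 0.1), rnorm(240, 5, 0.1))
  s <- make_series(dur, units = 5 * (1 + dur / 10))
  bp <- find_breakpoint(s)
  expect_lte(abs(bp$chosen - 60), 2)
  expect_equal(bp$chosen, max(bp$bp_time_series, bp$bp_units_series, na.rm = TRUE))
  expect_equal(bp$chosen_time_s, s$start_time_s[bp$chosen])

  const <- make_series(rep(10, 100), units = rnorm(100, 8, 1e-6))
  const$duration_s <- rnorm(100, 10, 1e-6)
  expect_error(find_breakpoint(const), class = "localwake_no_stabilization")
})

test_that("segmentation equals the exhaustive-search oracle on short series", {
  set.seed(22)
  for (rep in 1:5) {
    x <- c(rnorm(30, 0), rnorm(40, 2), rnorm(30, -1))
    fits <- localwake:::segment_mean_shift(x, k_max = 2L, min_seg = 5L)
    for (k in 1:2) {
      oracle <- oracle_segmentation(x, k, min_seg = 5L)
      expect_equal(fits[[k + 1]]$rss, oracle$rss, tolerance = 1e-9)
      expect_equal(fits[[k + 1]]$breaks, oracle$breaks)
    }
  }
})

test_that("classification applies fences, baseline and exclusion rules", {
  # toy route: post-breakpoint durations {10,10,10,10,30} -> 30 s trial is an error
  s <- make_series(c(rep(10, 16), 10, 10, 10, 10, 30))
  lab <- classify_retrievals(s, 16L)
  expect_identical(lab$labels[21], "error")
  expect_identical(unname(lab$labels[1:16]), rep("baseline", 16))

  # identical post-breakpoint durations -> IQR 0, zero errors
  s2 <- make_series(rep(10, 30))
  lab2 <- classify_retrievals(s2, 16L)
  expect_false(any(lab2$labels == "error"))

  # distraction flags are excluded and never errors
  s3 <- make_series(c(rep(10, 16), rep(10, 9), 40))
  s3$distraction[26] <- TRUE
  lab3 <- classify_retrievals(s3, 16L)
  expect_identical(lab3$labels[26], "excluded")

  # labels partition the series
  b <- gen_behavior(behavior_sim_config(seed = 31))
  bp <- find_breakpoint(b$series)
  lab4 <- suppressWarnings(classify_retrievals(b$series, bp))
  expect_equal(sum(lab4$counts), nrow(b$series))
  expect_false(any(lab4$labels == "error" & b$series$index <= bp$chosen))
})

test_that("error recovery from the synthetic generator is highly sensitive", {
  sens <- vapply(1:5, function(sd) {
    b <- gen_behavior(behavior_sim_config(seed = sd))
    bp <- find_breakpoint(b$series)
    lab <- suppressWarnings(classify_retrievals(b$series, bp))
    truth <- b$truth$true_error_index
    truth <- truth[truth > bp$chosen]
    length(intersect(which(lab$labels == "error"), truth)) / length(truth)
  }, numeric(1))
  expect_gte(mean(sens), 0.9)
})

test_that("interval partition produces equal half-open intervals anchored at the breakpoint", {
  # session of 100 min, breakpoint at 20 min
  s <- make_series(rep(60, 100))   # 100 retrievals x 1 min
  bp_idx <- 21L                    # starts at 1200 s = 20 min
  p2 <- partition_intervals(s, bp_idx, k = 2L)
  expect_equal(p2$boundaries, c(1200, 3600, 6000))
  p4 <- partition_intervals(s, bp_idx, k = 4L)
  expect_equal(diff(p4$boundaries), rep(1200, 4))
  # every post-breakpoint retrieval assigned exactly once
  post <- s$start_time_s >= 1200
  expect_false(any(is.na(p4$assignment[post])))
  expect_true(all(is.na(p4$assignment[!post])))
  expect_true(all(p4$assignment[post] %in% 1:4))
  # assignment consistent with boundaries
  for (i in which(post)) {
    iv <- p4$assignment[i]
    expect_gte(s$start_time_s[i], p4$boundaries[iv])
    if (iv < 4) expect_lt(s$start_time_s[i], p4$boundaries[iv + 1])
  }
})

test_that("retrieval series round-trips through CSV", {
  b <- gen_behavior(behavior_sim_config(seed = 41, n_retrievals = 40,
                                        true_breakpoint_index = 20))
  f <- tempfile(fileext = ".csv")
  write_retrieval_csv(b$series, f)
  back <- read_retrieval_csv(f)
  expect_equal(back$duration_s, b$series$duration_s, tolerance = 1e-12)
  expect_identical(back$route_label, b$series$route_label)
  unlink(f)
})
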