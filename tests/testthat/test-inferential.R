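test_that("one-tailed paired t matches hand computation and tail algebra", {
  x <- c(5.1, 6.2, 5.8, 7.0, 6.4)
  y <- c(4.8, 5.9, 6.0, 6.1, 5.9)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  r <- paired_t_one_tailed(x, y, "greater")
  expect_equal(r$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p, pt(t_hand, 4, lower.tail = FALSE), tolerance = 1e-12)
  r2 <- paired_t_one_tailed(x, y, "less")
  expect_equal(r2$p, 1 - r$p, tolerance = 1e-12)
  expect_error(paired_t_one_tailed(x, x), class = "localwake_degenerate")
  # Bonferroni correction is monotone and capped
  r3 <- paired_t_one_tailed(x, y, "greater", m = 100)
  expect_gte(r3$p_corrected, r3$p)
  expect_lte(r3$p_corrected, 1)
})

test_that("effect-size conversions reproduce the published worked examples", {
  expect_equal(round(d_from_paired_t(3.55, 20), 2), 1.12)
  expect_equal(round(d_from_paired_t(5.1191, 20), 2), 1.62)
  expect_equal(d_from_paired_t(0, 20), 0)
  expect_equal(round(d_from_r(0.58), 2), 1.42)
  expect_equal(round(d_from_r(-0.54), 2), 1.28)
  expect_equal(d_from_r(0), 0)
  expect_error(d_from_r(1), class = "localwake_domain_error")
})

test_that("Spearman correlations match a rank-then-Pearson oracle", {
  set.seed(61)
  x <- rnorm(10); y <- x + rnorm(10, sd = 0.6)
  res <- spearman_bonferroni(cbind(x, y), m = 3)[[1]]
  expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-10)
  expect_equal(res$p_corrected, min(1, 3 * res$p))
  mono <- spearman_bonferroni(cbind(1:8, (1:8)^3), m = 1)[[1]]
  expect_equal(mono$statistic, 1)
  expect_equal(spearman_bonferroni(cbind(x, y), m = 1)[[1]]$p_corrected,
               spearman_bonferroni(cbind(x, y), m = 1)[[1]]$p)
  expect_error(spearman_bonferroni(cbind(rep(1, 5), 1:5)),
               class = "localwake_degenerate")
})

test_that("Wilcoxon signed-rank with Pratt zeros matches exact enumeration", {
  d <- c(1.5, -0.5, 2, 3, -1, 0.5)
  r <- wilcoxon_signed_rank(d, exact_pratt = TRUE)
  rk <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  W_null <- apply(signs, 1, function(s) sum(rk[s > 0]))
  p_exact <- min(1, 2 * min(mean(W_null >= r$statistic), mean(W_null <= r$statistic)))
  expect_equal(r$p, p_exact, tolerance = 1e-12)

  # Pratt: zeros are ranked, then dropped
  dz <- c(0, 0, 1, -2, 3, 4, -1.5)
  rz <- wilcoxon_signed_rank(dz, exact_pratt = TRUE)
  expect_equal(rz$n, 5)
  rk_all <- rank(abs(dz))
  expect_equal(rz$statistic, sum(rk_all[dz > 0]))

  # a large uniform shift attains the minimal exact p
  big <- wilcoxon_signed_rank(rep(3, 8) + rnorm(8, sd = 0.1), exact_pratt = TRUE)
  expect_equal(big$p, 2 * (1 / 2^8), tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(rep(0, 6)), class = "localwake_degenerate")
})

test_that("exact Wilcoxon p values are valid and calibrated under a symmetric null", {
  set.seed(62)
  ps <- vapply(1:1000, function(i)
    wilcoxon_signed_rank(rnorm(12), exact_pratt = TRUE)$p, numeric(1))
  # exact discrete p values: P(p <= a) <= a, and close to a at moderate a
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    hit <- mean(ps <= a)
    expect_lte(hit, a + 3 * sqrt(a * (1 - a) / 1000))
    expect_gte(hit, a - 0.05 - 3 * sqrt(a * (1 - a) / 1000))
  }
})

test_that("ranked RANCOVA is calibrated under the null and powered under a shift", {
  set.seed(63)
  fs <- replicate(60, {
    pre <- rnorm(30); post <- 0.5 * pre + rnorm(30)
    g <- factor(rep(c("a", "b"), 15))
    ranked_rancova(pre, post, g)$statistic
  })
  expect_equal(mean(fs), 1, tolerance = 0.35)      # E[F] ~ df2/(df2-2) ~ 1.08
  hits <- mean(replicate(50, {
    pre <- rnorm(40)
    post <- 0.5 * pre + rnorm(40)
    g <- factor(rep(c("a", "b"), each = 20))
    post[g == "b"] <- post[g == "b"] + sd(post)
    ranked_rancova(pre, post, g)$p < 0.05
  }))
  expect_gte(hits, 0.8)
  # least-squares residuals used internally sum to zero
  pre <- rnorm(20); post <- rnorm(20)
  expect_equal(sum(resid(lm(rank(post) ~ rank(pre)))), 0, tolerance = 1e-10)
  expect_error(ranked_rancova(rnorm(3), rnorm(3), factor(c("a", "a", "b"))),
               class = "localwake_insufficient_data")
})

test_that("PVT metrics follow the lapse and reciprocal-RT conventions", {
  r <- pvt_metrics(rep(250, 20))
  expect_equal(r$n_lapses, 0)
  expect_equal(r$mean_recip_rt, 4)
  expect_equal(r$slowest10_recip_rt, 4)
  expect_equal(pvt_metrics(c(rep(200, 9), 600))$n_lapses, 1)
  set.seed(64)
  rt <- runif(200, 180, 700)
  r2 <- pvt_metrics(rt)
  q90 <- quantile(rt, 0.9, type = 7, names = FALSE)
  expect_equal(r2$slowest10_recip_rt, mean(1000 / sort(rt[rt >= q90])), tolerance = 1e-12)
  expect_lte(r2$slowest10_recip_rt, r2$mean_recip_rt)
  expect_equal(r2$n_lapses, sum(rt >= 500))
  expect_error(pvt_metrics(c(200, -5)), class = "localwake_domain_error")
})
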