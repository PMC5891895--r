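#' One-tailed paired t test
#'
#' Paired t over the differences `x - y`, with the alternative in the stated
#' direction; the two-group-equivalent Cohen's d is attached.
#'
#' @param x,y paired samples.
#' @param direction `"greater"` (mean of x exceeds y) or `"less"`.
#' @param m Bonferroni family size for the corrected p.
#' @return list of class `test_result`: `statistic`, `df`, `p`,
#'   `p_corrected`, `effect_size`, `test`.
#' @export
paired_t_one_tailed <- function(x, y, direction = c("greater", "less"), m = 1L) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x - y) == 0)
    stop_localwake("zero-variance differences: t undefined", "localwake_degenerate")
  tt <- t.test(x, y, paired = TRUE, alternative = direction)
  n <- length(x)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, p_corrected = min(1, m * tt$p.value),
                 effect_size = d_from_paired_t(unname(tt$statistic), n),
                 test = "one-tailed paired t"),
            class = "test_result")
}

#' Cohen's d from a paired t statistic
#'
#' Uses the two-group-equivalent conversion `d = |t| * sqrt(2 / n)`, the
#' convention of standard effect-size calculators for paired designs.
#'
#' @param t t statistic.
#' @param n number of pairs.
#' @return nonnegative effect size.
#' @export
d_from_paired_t <- function(t, n) {
  stopifnot(n >= 2)
  abs(t) * sqrt(2 / n)
}

#' Cohen's d from a correlation coefficient
#'
#' `d = 2 |r| / sqrt(1 - r^2)`.
#'
#' @param r correlation in (-1, 1).
#' @return nonnegative effect size.
#' @export
d_from_r <- function(r) {
  if (abs(r) >= 1)
    stop_localwake("|r| must be below 1", "localwake_domain_error")
  2 * abs(r) / sqrt(1 - r^2)
}

#' Spearman correlations with Bonferroni correction
#'
#' Rank correlation with average ranks for ties; p values from the
#' t approximation; the corrected p is `min(1, m * p)` and the attached
#' effect size is [d_from_r()].
#'
#' @param pairs list of two-column data.frames/matrices (or a single one).
#' @param m family size (defaults to the number of pairs).
#' @return list of `test_result` objects (fields `statistic` = rho, `n`,
#'   `p`, `p_corrected`, `effect_size`).
#' @export
spearman_bonferroni <- function(pairs, m = NULL) {
  if (is.data.frame(pairs) || is.matrix(pairs)) pairs <- list(pairs)
  m <- m %||% length(pairs)
  lapply(pairs, function(xy) {
    x <- xy[, 1]; y <- xy[, 2]
    stopifnot(length(x) >= 4)
    if (sd(x) == 0 || sd(y) == 0)
      stop_localwake("constant series: rho undefined", "localwake_degenerate")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    structure(list(statistic = rho, n = length(x), p = ct$p.value,
                   p_corrected = min(1, m * ct$p.value),
                   effect_size = if (abs(rho) < 1) d_from_r(rho) else Inf,
                   test = "Spearman rho (Bonferroni)"),
              class = "test_result")
  })
}

# exact null distribution of the positive-rank sum W+ over sign assignments
# of the given ranks; ranks may be half-integers (average ranks under ties),
# so the convolution runs on a doubled integer grid.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1L)  # index i -> P(2 W+ = i - 1)
  dist[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  dist
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Ranks the absolute differences including zeros (average ranks), then
#' drops the zero differences (Pratt). The statistic is the positive-rank
#' sum W. With `exact_pratt = TRUE` and at most `max_exact` nonzero pairs
#' the null distribution of W is enumerated exactly by convolution over the
#' retained ranks; otherwise a normal approximation with continuity
#' correction is used (ties enter through the actual ranks).
#'
#' @param x,y paired samples (`y` optional: one-sample differences).
#' @param exact_pratt use the exact enumeration when feasible?
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param max_exact largest n for exact enumeration.
#' @return list of class `test_result`: `statistic` (W), `z`, `n` (nonzero
#'   pairs), `p`, `test`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_pratt = FALSE,
                                 alternative = c("two.sided", "greater", "less"),
                                 max_exact = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  if (all(d == 0))
    stop_localwake("all differences are zero", "localwake_degenerate")
  r_all <- rank(abs(d))            # zeros included in the ranking (Pratt)
  nz <- d != 0
  if (sum(nz) < 3)
    stop_localwake("fewer than 3 nonzero differences", "localwake_degenerate")
  r <- r_all[nz]
  s <- sign(d[nz])
  W <- sum(r[s > 0])
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  z <- (W - mu) / sigma
  if (exact_pratt && sum(nz) <= max_exact) {
    dist <- signed_rank_null(r)
    idx <- as.integer(round(2 * W)) + 1L
    p_ge <- sum(dist[idx:length(dist)])
    p_le <- sum(dist[seq_len(idx)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_ge, p_le)),
                greater = p_ge,
                less = p_le)
    method <- "exact Wilcoxon-Pratt signed-rank"
  } else {
    cc <- 0.5 / sigma
    p <- switch(alternative,
                two.sided = 2 * pnorm(abs(z) - cc, lower.tail = FALSE),
                greater = pnorm(z - cc, lower.tail = FALSE),
                less = pnorm(z + cc))
    p <- min(1, max(0, p))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  structure(list(statistic = W, z = z, n = sum(nz), p = p, test = method),
            class = "test_result")
}

#' Nonparametric ranked analysis of covariance
#'
#' Ranks the pre-test and post-test measures separately, ignoring group;
#' regresses the post-test ranks on the pre-test ranks by least squares; and
#' runs a one-way ANOVA of the regression residuals (residual rank scores)
#' on the group factor.
#'
#' @param pre,post numeric vectors, one value per subject.
#' @param group factor (two or more groups, each with >= 2 subjects).
#' @return list of class `test_result`: `statistic` (F), `df` (numerator,
#'   denominator), `p`, `test`.
#' @export
ranked_rancova <- function(pre, post, group) {
  stopifnot(length(pre) == length(post), length(pre) == length(group))
  group <- droplevels(as.factor(group))
  if (any(table(group) < 2))
    stop_localwake("each group needs at least 2 subjects", "localwake_insufficient_data")
  r_pre <- rank(pre)
  r_post <- rank(post)
  res <- resid(lm(r_post ~ r_pre))
  av <- anova(aov(res ~ group))
  structure(list(statistic = av[["F value"]][1],
                 df = c(av$Df[1], av$Df[2]),
                 p = av[["Pr(>F)"]][1],
                 test = "ranked RANCOVA (residual rank scores)"),
            class = "test_result")
}

#' Psychomotor vigilance task summary metrics
#'
#' Lapses are reaction times at or above the conventional 500 ms cutoff.
#' Response speed is summarized as the mean reciprocal reaction time (1/s)
#' and the mean reciprocal reaction time over the slowest decile (reaction
#' times at or above the linearly interpolated 90th percentile).
#'
#' @param rt_ms reaction times in milliseconds.
#' @param lapse_ms lapse threshold (ms).
#' @return list of class `pvt_metrics`: `n_lapses`, `mean_recip_rt`,
#'   `slowest10_recip_rt`, `n`.
#' @export
pvt_metrics <- function(rt_ms, lapse_ms = 500) {
  if (length(rt_ms) == 0 || any(rt_ms <= 0))
    stop_localwake("reaction times must be positive", "localwake_domain_error")
  q90 <- quantile(rt_ms, 0.9, type = 7, names = FALSE)
  slowest <- rt_ms[rt_ms >= q90]
  structure(list(n_lapses = sum(rt_ms >= lapse_ms),
                 mean_recip_rt = mean(1000 / rt_ms),
                 slowest10_recip_rt = mean(1000 / slowest),
                 n = length(rt_ms)),
            class = "pvt_metrics")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, p = %.4g\n", x$test,
              x$statistic, x$p))
  invisible(x)
}
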