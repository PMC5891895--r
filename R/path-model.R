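#' Repetition-dependent improvement before the first error
#'
#' Computes, per subject, the deviation from the optimal path over the
#' retrievals preceding the first error (excluding the baseline retrievals),
#' separately per route type, and combines the route values by a weighted
#' average with the per-route best-hit counts before the first error as
#' weights. The default composition then divides by the number of
#' pre-first-error repetitions, yielding a per-repetition improvement rate;
#' the alternative `"product"` composition multiplies the unweighted mean
#' deviation by the best-hit fraction per repetition. When no best hits
#' precede the first error the weights fall back to equal, with a warning.
#'
#' @param series a `retrieval_series`.
#' @param labels a `labeled_series` for the same subject.
#' @param n_baseline baseline retrievals excluded from the computation.
#' @param composition `"rate"` (default) or `"product"`.
#' @return list: `improvement`, `first_error_index`, `first_error_time_s`
#'   (the use-dependent saturation point), `n_repetitions`, `route_table`.
#' @export
build_improvement <- function(series, labels, n_baseline = 16L,
                              composition = c("rate", "product")) {
  composition <- match.arg(composition)
  stopifnot(inherits(labels, "labeled_series"))
  err_idx <- which(labels$labels == "error")
  if (length(err_idx) == 0)
    stop_localwake("subject committed no errors; excluded from path data",
                   "localwake_no_errors")
  first_err <- min(err_idx)
  pre <- series$index > n_baseline & series$index < first_err &
    labels$labels != "excluded"
  if (!any(pre))
    stop_localwake("no retrievals between baseline and first error",
                   "localwake_insufficient_data")
  sub <- series[pre, , drop = FALSE]
  routes <- unique(sub$route_label)
  dev <- vapply(routes, function(rt)
    deviation_from_optimal(sub[sub$route_label == rt, , drop = FALSE]), numeric(1))
  bh <- vapply(routes, function(rt)
    sum(labels$labels[pre] == "best_hit" & series$route_label[pre] == rt), numeric(1))
  if (sum(bh) == 0) {
    warning("no best hits before the first error; equal route weights used")
    bh <- rep(1, length(routes))
  }
  n_rep <- nrow(sub)
  improvement <- switch(composition,
    rate = sum(dev * bh) / sum(bh) / n_rep,
    product = mean(dev) * sum(bh) / n_rep)
  list(improvement = improvement,
       first_error_index = first_err,
       first_error_time_s = series$start_time_s[first_err],
       n_repetitions = n_rep,
       route_table = data.frame(route_label = routes, deviation = dev,
                                best_hits = bh, row.names = NULL))
}

# implied covariance of the recursive 4-variable chain
chain_implied_cov <- function(beta, psi) {
  B <- matrix(0, 4, 4)
  B[2, 1] <- beta[1]; B[3, 2] <- beta[2]; B[4, 3] <- beta[3]
  Ii <- solve(diag(4) - B)
  Ii %*% diag(psi) %*% t(Ii)
}

ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(determinant(Sigma)$modulus) - as.numeric(determinant(S)$modulus) +
    sum(diag(S %*% solve(Sigma))) - p
}

#' Fit the learning-related use-dependent local sleep path model
#'
#' Fits the recursive chain improvement -> saturation -> local_sleep ->
#' errors by maximum likelihood on the implied versus observed covariance
#' matrix of the standardized variables. For this recursive observed-variable
#' chain the ML point estimates coincide with per-equation least squares
#' (verified internally); the free parameters are the three path
#' coefficients and four residual variances, leaving df = 10 - 7 = 3.
#'
#' Fit indices: chi-square `(n - 1) * F_ML`; SRMR (root mean squared
#' standardized covariance residual over the unique elements); RMSEA
#' `sqrt(max(chi2 - df, 0) / (df * (n - 1)))`; CFI against the independence
#' model; AIC on the `-2 logL + 2k` convention for the fitted (k = 7) and
#' saturated (k = 10) models.
#'
#' @param data data.frame with columns `improvement`, `saturation`,
#'   `local_sleep`, `errors` (one row per subject), or `NULL` when `cov` is
#'   given.
#' @param cov optional covariance (or correlation) matrix of the four
#'   variables, bypassing `data`.
#' @param n sample size (required with `cov`).
#' @return list of class `path_fit`: `betas`, `se`, `p`, `psi`, `chi2`,
#'   `df`, `p_chi2`, `srmr`, `rmsea`, `cfi`, `aic_model`, `aic_saturated`,
#'   `n`.
#' @export
fit_path_model <- function(data = NULL, cov = NULL, n = NULL) {
  vars <- c("improvement", "saturation", "local_sleep", "errors")
  if (is.null(cov)) {
    stopifnot(is.data.frame(data), all(vars %in% names(data)))
    data <- data[stats::complete.cases(data[vars]), vars]
    n <- nrow(data)
    if (n < 10)
      stop_localwake("need at least 10 complete rows", "localwake_insufficient_data")
    if (any(vapply(data, sd, numeric(1)) == 0))
      stop_localwake("zero-variance variable", "localwake_degenerate")
    Z <- scale(as.matrix(data))
    S <- stats::cov(Z)
  } else {
    stopifnot(!is.null(n), all(dim(cov) == c(4, 4)))
    Ds <- diag(1 / sqrt(diag(cov)))
    S <- Ds %*% cov %*% Ds    # standardized metric
    dimnames(S) <- list(vars, vars)
  }
  if (abs(det(S)) < 1e-12)
    stop_localwake("singular covariance matrix", "localwake_estimation_error")

  beta <- numeric(3); se <- numeric(3); pval <- numeric(3); psi <- numeric(4)
  psi[1] <- S[1, 1]
  for (j in 1:3) {
    beta[j] <- S[j + 1, j] / S[j, j]
    psi[j + 1] <- S[j + 1, j + 1] - beta[j]^2 * S[j, j]
    # classical OLS standard error in the standardized metric
    se[j] <- sqrt(psi[j + 1] / S[j, j] / (n - 2))
    tstat <- beta[j] / se[j]
    pval[j] <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  Sigma <- chain_implied_cov(beta, psi)
  f_ml <- max(0, ml_discrepancy(S, Sigma))
  df <- 3
  chi2 <- (n - 1) * f_ml
  p_chi2 <- stats::pchisq(chi2, df, lower.tail = FALSE)

  Dh <- sqrt(diag(S))
  res <- (S - Sigma) / outer(Dh, Dh)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))

  Sigma0 <- diag(diag(S))
  chi2_0 <- (n - 1) * ml_discrepancy(S, Sigma0)
  df0 <- 6
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_0 - df0, chi2 - df, 0)
  cfi <- min(1, max(0, cfi))

  # -2 logL + 2k with the normal likelihood at the ML-scaled sample cov
  Sn <- S * (n - 1) / n
  p <- 4
  loglik <- function(Sig) -(n / 2) * (p * log(2 * pi) +
    as.numeric(determinant(Sig)$modulus) + sum(diag(Sn %*% solve(Sig))))
  aic_model <- -2 * loglik(Sigma) + 2 * 7
  aic_sat <- -2 * loglik(Sn) + 2 * 10

  structure(list(betas = setNames(beta, c("saturation~improvement",
                                          "local_sleep~saturation",
                                          "errors~local_sleep")),
                 se = se, p = pval, psi = psi,
                 chi2 = chi2, df = df, p_chi2 = p_chi2,
                 srmr = srmr, rmsea = rmsea, cfi = cfi,
                 aic_model = aic_model, aic_saturated = aic_sat, n = n),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("<path_fit> learning-related use-dependent local sleep model\n")
  for (i in 1:3)
    cat(sprintf("  %-24s beta = %6.3f (se %.3f, p = %.4g)\n",
                names(x$betas)[i], x$betas[i], x$se[i], x$p[i]))
  cat(sprintf("  chi2(%d) = %.3f, p = %.3f | SRMR %.3f | RMSEA %.3f | CFI %.3f\n",
              x$df, x$chi2, x$p_chi2, x$srmr, x$rmsea, x$cfi))
  cat(sprintf("  AIC model %.3f vs saturated %.3f\n", x$aic_model, x$aic_saturated))
  invisible(x)
}
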