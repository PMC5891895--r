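#' Generate standardized data from the recursive path-model chain
#'
#' Simulates the four observed variables of the learning-related
#' use-dependent local sleep model along the causal chain
#' improvement -> saturation -> local_sleep -> errors. Each variable is
#' standardized in the population: the first is standard normal and each
#' successor is `beta * parent + sqrt(1 - beta^2) * noise`, so all variables
#' have unit variance and the implied correlation between variables j steps
#' apart is the product of the intervening betas.
#'
#' @param true_betas numeric length 3, each with absolute value below 1:
#'   the standardized coefficients of the three chained regressions.
#' @param n sample size (>= 10).
#' @param seed integer seed.
#' @return data.frame with columns `improvement`, `saturation`,
#'   `local_sleep`, `errors` and attribute `true_betas`.
#' @export
gen_path_data <- function(true_betas, n, seed = NULL) {
  if (length(true_betas) != 3 || any(!is.finite(true_betas)))
    stop_localwake("true_betas must be three finite coefficients",
                   "localwake_invalid_config")
  if (any(abs(true_betas) >= 1))
    stop_localwake("|beta| must be < 1 for unit-variance generation",
                   "localwake_invalid_config")
  if (n < 10)
    stop_localwake("n must be at least 10", "localwake_invalid_config")
  if (!is.null(seed)) set.seed(seed)
  b <- true_betas
  improvement <- rnorm(n)
  saturation <- b[1] * improvement + sqrt(1 - b[1]^2) * rnorm(n)
  local_sleep <- b[2] * saturation + sqrt(1 - b[2]^2) * rnorm(n)
  errors <- b[3] * local_sleep + sqrt(1 - b[3]^2) * rnorm(n)
  out <- data.frame(improvement = improvement, saturation = saturation,
                    local_sleep = local_sleep, errors = errors)
  attr(out, "true_betas") <- b
  out
}
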