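#' Default wayfinding maze routes
#'
#' Eight landmark pairs on a 100 x 100 maze-unit grid. Start/end coordinates
#' define each route's optimal path length (straight-line distance).
#'
#' @return data.frame with columns `route_label`, `x1`, `z1`, `x2`, `z2`.
#' @export
default_routes <- function() {
  data.frame(
    route_label = paste0("R", 1:8),
    x1 = c(10, 90, 20, 75, 50, 15, 85, 40),
    z1 = c(10, 15, 80, 85, 10, 50, 50, 40),
    x2 = c(70, 30, 85, 15, 55, 80, 20, 45),
    z2 = c(60, 75, 25, 20, 90, 85, 15, 95),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic wayfinding session
#'
#' Defaults emulate the study conditions of the wayfinding experiment: a
#' ~2 h session of 295 contiguous retrievals over 8 route types, the first 16
#' retrievals forming the baseline, performance stabilizing at a breakpoint
#' near retrieval 62, and outlier errors (inflated duration and path units)
#' whose probability rises in the second temporal half of the post-breakpoint
#' period.
#'
#' Before the breakpoint mean duration/excess decline gently (a fraction
#' `ramp_fraction` of the baseline-to-stable gap), with the remaining drop
#' occurring at the breakpoint itself; after it both series are stationary.
#'
#' @param n_retrievals total retrievals in the session.
#' @param n_route_types number of distinct routes (cycled in blocks).
#' @param n_baseline number of initial baseline retrievals.
#' @param true_breakpoint_index retrieval index at which performance stabilizes.
#' @param baseline_duration_mean,baseline_duration_sd seconds, pre-stabilization.
#' @param stable_duration_mean,stable_duration_sd seconds, post-stabilization.
#' @param ramp_fraction fraction of the baseline-to-stable drop that accrues
#'   gradually before the breakpoint (the rest is a step at the breakpoint).
#' @param baseline_excess,stable_excess mean fractional path-length excess over
#'   the optimal route before/after stabilization.
#' @param excess_sd trial-to-trial sd of the fractional excess.
#' @param error_prob_first_half,error_prob_second_half probability that a
#'   post-breakpoint retrieval is an error, by temporal half.
#' @param error_inflation_factor multiplier applied to duration and units on
#'   error trials (errors are outliers in time and units).
#' @param distraction_prob probability a retrieval is flagged as a distraction
#'   (eyes closed / looked away) and must be excluded downstream.
#' @param routes route table as from [default_routes()].
#' @param seed integer seed; the generator is deterministic given it.
#' @return list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_retrievals = 295L,
                                n_route_types = 8L,
                                n_baseline = 16L,
                                true_breakpoint_index = 62L,
                                baseline_duration_mean = 45,
                                baseline_duration_sd = 4,
                                stable_duration_mean = 20,
                                stable_duration_sd = 2.5,
                                ramp_fraction = 0.2,
                                baseline_excess = 1.0,
                                stable_excess = 0.10,
                                excess_sd = 0.08,
                                error_prob_first_half = 0.10,
                                error_prob_second_half = 0.24,
                                error_inflation_factor = 3,
                                distraction_prob = 0.01,
                                routes = default_routes(),
                                seed = NULL) {
  cfg <- list(
    n_retrievals = as.integer(n_retrievals),
    n_route_types = as.integer(n_route_types),
    n_baseline = as.integer(n_baseline),
    true_breakpoint_index = as.integer(true_breakpoint_index),
    baseline_duration_mean = baseline_duration_mean,
    baseline_duration_sd = baseline_duration_sd,
    stable_duration_mean = stable_duration_mean,
    stable_duration_sd = stable_duration_sd,
    ramp_fraction = ramp_fraction,
    baseline_excess = baseline_excess,
    stable_excess = stable_excess,
    excess_sd = excess_sd,
    error_prob_first_half = error_prob_first_half,
    error_prob_second_half = error_prob_second_half,
    error_inflation_factor = error_inflation_factor,
    distraction_prob = distraction_prob,
    routes = routes,
    seed = seed
  )
  probs <- c(cfg$error_prob_first_half, cfg$error_prob_second_half,
             cfg$distraction_prob)
  if (any(probs < 0 | probs > 1))
    stop_localwake("probabilities must lie in [0, 1]", "localwake_invalid_config")
  if (cfg$baseline_duration_mean <= 0 || cfg$stable_duration_mean <= 0)
    stop_localwake("durations must be strictly positive", "localwake_invalid_config")
  if (cfg$n_retrievals < cfg$n_route_types)
    stop_localwake("n_retrievals < n_route_types", "localwake_invalid_config")
  if (cfg$error_inflation_factor <= 1)
    stop_localwake("error_inflation_factor must exceed 1", "localwake_invalid_config")
  if (cfg$true_breakpoint_index <= cfg$n_baseline ||
      cfg$true_breakpoint_index >= cfg$n_retrievals)
    stop_localwake("true_breakpoint_index must lie strictly between the baseline and the session end",
                   "localwake_invalid_config")
  if (nrow(cfg$routes) < cfg$n_route_types)
    stop_localwake("route table smaller than n_route_types", "localwake_invalid_config")
  class(cfg) <- "behavior_sim_config"
  cfg
}

#' Generate a synthetic wayfinding retrieval series with ground truth
#'
#' Produces a contiguous retrieval series (each retrieval starts when the
#' previous one ends) whose duration and path-unit series follow a gently
#' decreasing trend before the configured breakpoint and a stationary
#' distribution after it. Post-breakpoint retrievals are flagged as errors
#' with half-specific probabilities; error trials have duration and units
#' multiplied by `error_inflation_factor`.
#'
#' @param config a [behavior_sim_config()].
#' @return list with `series` (data.frame of class `retrieval_series`: columns
#'   `index`, `route_label`, `x1`, `z1`, `x2`, `z2`, `start_time_s`,
#'   `duration_s`, `units`, `distraction`) and `truth` (list: `true_labels`,
#'   `true_breakpoint`, `true_error_index`, `config`).
#' @export
gen_behavior <- function(config = behavior_sim_config()) {
  stopifnot(inherits(config, "behavior_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_retrievals
  bp <- config$true_breakpoint_index
  routes <- config$routes[seq_len(config$n_route_types), , drop = FALSE]

  # route order: baseline passes first, then repeated blocks of the route set
  order_idx <- rep(seq_len(config$n_route_types), length.out = n)
  rt <- routes[order_idx, , drop = FALSE]
  optimal <- sqrt((rt$x1 - rt$x2)^2 + (rt$z1 - rt$z2)^2)

  # mean trajectories: gentle ramp before bp, level after
  gap_d <- config$baseline_duration_mean - config$stable_duration_mean
  gap_e <- config$baseline_excess - config$stable_excess
  idx <- seq_len(n)
  ramp <- pmin(idx / bp, 1)
  mean_dur <- ifelse(idx <= bp,
                     config$baseline_duration_mean - config$ramp_fraction * gap_d * ramp,
                     config$stable_duration_mean)
  mean_exc <- ifelse(idx <= bp,
                     config$baseline_excess - config$ramp_fraction * gap_e * ramp,
                     config$stable_excess)
  dur_sd <- ifelse(idx <= bp, config$baseline_duration_sd, config$stable_duration_sd)

  duration <- pmax(1, rnorm(n, mean_dur, dur_sd))
  excess <- pmax(0.02, rnorm(n, mean_exc, config$excess_sd))
  units <- optimal * (1 + excess)

  # temporal halves of the post-breakpoint period on the uninflated timeline
  start0 <- cumsum(c(0, duration[-n]))
  post <- idx > bp
  bp_time <- start0[bp]
  mid_time <- bp_time + (start0[n] + duration[n] - bp_time) / 2
  second_half <- post & start0 >= mid_time

  err_p <- ifelse(second_half, config$error_prob_second_half,
                  config$error_prob_first_half)
  is_error <- post & (runif(n) < err_p)
  duration[is_error] <- duration[is_error] * config$error_inflation_factor
  units[is_error] <- units[is_error] * config$error_inflation_factor

  distraction <- runif(n) < config$distraction_prob
  start <- cumsum(c(0, duration[-n]))

  labels <- ifelse(idx <= config$n_baseline, "baseline",
                   ifelse(idx <= bp, "pre_stable",
                          ifelse(is_error, "error", "hit")))
  series <- data.frame(
    index = idx,
    route_label = rt$route_label,
    x1 = rt$x1, z1 = rt$z1, x2 = rt$x2, z2 = rt$z2,
    start_time_s = start,
    duration_s = duration,
    units = units,
    distraction = distraction,
    stringsAsFactors = FALSE
  )
  class(series) <- c("retrieval_series", "data.frame")
  truth <- list(
    true_labels = labels,
    true_breakpoint = bp,
    true_second_half = second_half,
    true_error_index = which(is_error),
    config = config
  )
  list(series = series, truth = truth)
}
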