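#' Optimal path length of a route
#'
#' The optimal path is the straight-line (Euclidean) distance between the
#' start and end landmark of a route, in maze units.
#'
#' @param start_xy,end_xy numeric length-2 coordinates (x, z).
#' @return nonnegative distance; symmetric in its arguments.
#' @export
optimal_path_length <- function(start_xy, end_xy) {
  if (!all(is.finite(c(start_xy, end_xy))))
    stop_localwake("coordinates must be finite", "localwake_domain_error")
  sqrt(sum((start_xy - end_xy)^2))
}

#' Mean percentage deviation from the optimal path
#'
#' For records i = 1..N computes `mean((optimal_i - units_i) / optimal_i) * 100`.
#' Since the traveled units can never be shorter than the straight line, the
#' value is nonpositive; improvement toward the optimum moves it toward 0.
#'
#' @param records data.frame with columns `x1`, `z1`, `x2`, `z2`, `units`
#'   (a subset of a `retrieval_series`).
#' @return percentage deviation (scalar, <= 0 when all units >= optimal).
#' @export
deviation_from_optimal <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    stop_localwake("empty record set", "localwake_domain_error")
  optimal <- sqrt((records$x1 - records$x2)^2 + (records$z1 - records$z2)^2)
  if (any(optimal <= 0))
    stop_localwake("degenerate route with optimal length 0", "localwake_degenerate_route")
  mean((optimal - records$units) / optimal) * 100
}

# Exact least-squares segmentation of a series into mean-shift segments.
# Dynamic programming over O(n^2) segment costs computed from cumulative
# sums; returns for each number of breaks k = 0..k_max the minimal residual
# sum of squares and the break positions (last index of each segment).
segment_mean_shift <- function(x, k_max = 3L, min_seg = 2L) {
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  segcost <- function(i, j) {
    # cost of segment (i+1)..j for vectors i (0-based start) and scalar j
    len <- j - i
    s <- cs[j] - ifelse(i > 0, cs[i], 0)
    q <- cs2[j] - ifelse(i > 0, cs2[i], 0)
    q - s^2 / len
  }
  # C[k+1, j]: min RSS of x[1..j] split into k+1 segments
  C <- matrix(Inf, nrow = k_max + 1L, ncol = n)
  B <- array(NA_integer_, dim = c(k_max + 1L, n))  # last break before j
  j_all <- seq_len(n)
  C[1, ] <- vapply(j_all, function(j) if (j >= min_seg) segcost(0L, j) else Inf, numeric(1))
  for (k in seq_len(k_max)) {
    for (j in j_all) {
      if (j < (k + 1L) * min_seg) next
      i_cand <- seq(k * min_seg, j - min_seg)  # break positions (end of previous part)
      tot <- C[k, i_cand] + segcost(i_cand, j)
      w <- which.min(tot)
      C[k + 1L, j] <- tot[w]
      B[k + 1L, j] <- i_cand[w]
    }
  }
  res <- vector("list", k_max + 1L)
  for (k in 0:k_max) {
    if (!is.finite(C[k + 1L, n])) { res[[k + 1L]] <- NULL; next }
    breaks <- integer(0)
    j <- n
    kk <- k
    while (kk > 0L) {
      j <- B[kk + 1L, j]
      breaks <- c(j, breaks)
      kk <- kk - 1L
    }
    res[[k + 1L]] <- list(k = k, rss = C[k + 1L, n], breaks = breaks)
  }
  res
}

# BIC for a k-break mean-shift model: (k+1) segment means, k positions, one
# variance.
segmentation_bic <- function(rss, n, k) {
  n * log(pmax(rss, 1e-12) / n) + (2 * k + 2) * log(n)
}

#' Detect the performance breakpoint of a retrieval series
#'
#' Standardizes the duration and path-unit series separately — within route
#' type, since routes differ in length — then fits each standardized series
#' with an exact least-squares mean-shift segmentation for 0..`k_max`
#' breaks, selects the number of breaks by BIC, and takes the first break of
#' each series. The chosen breakpoint is the farther of the two from the
#' start of the series; performance is considered stable after it.
#'
#' @param series a `retrieval_series` data.frame.
#' @param k_max maximal number of breaks considered per series.
#' @param min_seg minimal segment length (retrievals); by default 15 % of
#'   the series (the conventional trimming of least-squares break estimation),
#'   floored at 8.
#' @param min_len minimal series length.
#' @return list of class `breakpoint_result`: `bp_time_series`,
#'   `bp_units_series` (first break index per series, NA when BIC selects 0
#'   breaks), `chosen` (retrieval index), `chosen_time_s`.
#' @export
find_breakpoint <- function(series, k_max = 3L, min_seg = NULL, min_len = 20L) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < min_len)
    stop_localwake("series shorter than the configured minimum", "localwake_domain_error")
  min_seg <- min_seg %||% max(8L, floor(0.15 * nrow(series)))
  grp <- series$route_label %||% rep("all", nrow(series))
  first_break <- function(x) {
    z <- stats::ave(x, grp, FUN = function(v)
      if (length(v) > 1 && sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v))
    if (sd(z) == 0) return(NA_integer_)
    fits <- segment_mean_shift(z, k_max = k_max, min_seg = min_seg)
    fits <- fits[!vapply(fits, is.null, logical(1))]
    bic <- vapply(fits, function(f) segmentation_bic(f$rss, length(z), f$k), numeric(1))
    best <- fits[[which.min(bic)]]
    if (best$k == 0L) NA_integer_ else best$breaks[1L]
  }
  bp_t <- first_break(series$duration_s)
  bp_u <- first_break(series$units)
  if (is.na(bp_t) && is.na(bp_u))
    stop_localwake("no stabilization: BIC selects zero breaks in both series",
                   "localwake_no_stabilization")
  chosen <- max(bp_t, bp_u, na.rm = TRUE)
  structure(list(bp_time_series = bp_t, bp_units_series = bp_u,
                 chosen = chosen,
                 chosen_time_s = series$start_time_s[chosen]),
            class = "breakpoint_result")
}

#' Classify retrievals into baseline, hits, best hits and errors
#'
#' The first `n_baseline` retrievals are the baseline; distraction-flagged
#' retrievals (after the baseline) are excluded. Post-breakpoint retrievals
#' whose duration or path units exceed the Tukey upper fence
#' (Q3 + `fence_k` * IQR), computed per route type over that subject's
#' post-breakpoint retrievals, are errors (outliers in time and units).
#' Among the remaining post-breakpoint hits, the retrieval(s) attaining the
#' route minimum are best hits. Pre-breakpoint non-baseline retrievals are
#' labeled `pre_stable`.
#'
#' @param series a `retrieval_series`.
#' @param breakpoint a `breakpoint_result` (or retrieval index).
#' @param outlier_rule `"or"` (default: outlier in time OR units) or `"and"`.
#' @param best_hit_rule `"either"` (route minimum in units or in time;
#'   default) or `"both"` (must attain both minima).
#' @param fence_k multiplier of the IQR above Q3 (1.5 = Tukey fence). A zero
#'   IQR yields no outliers.
#' @param fence_scope `"pooled_z"` (default): duration and units are
#'   standardized within route type over the post-breakpoint retrievals and
#'   a single fence is computed on each pooled standardized series —
#'   robust when a single route happens to accumulate many errors;
#'   `"per_route"`: fences computed per route on the raw values.
#' @param n_baseline number of initial baseline retrievals.
#' @param min_route_n minimal post-breakpoint retrievals of a route for its
#'   quartiles to be defined; smaller routes are skipped with a warning
#'   (`per_route` scope only).
#' @return list of class `labeled_series`: `labels` (character vector),
#'   `counts` (table), `breakpoint` (index).
#' @export
classify_retrievals <- function(series, breakpoint,
                                outlier_rule = c("or", "and"),
                                best_hit_rule = c("either", "both"),
                                fence_k = 1.5,
                                fence_scope = c("pooled_z", "per_route"),
                                n_baseline = 16L,
                                min_route_n = 4L) {
  outlier_rule <- match.arg(outlier_rule)
  best_hit_rule <- match.arg(best_hit_rule)
  fence_scope <- match.arg(fence_scope)
  bp <- if (inherits(breakpoint, "breakpoint_result")) breakpoint$chosen else as.integer(breakpoint)
  n <- nrow(series)
  stopifnot(bp >= 1, bp <= n)
  labels <- rep(NA_character_, n)
  labels[seq_len(min(n_baseline, n))] <- "baseline"
  excl <- series$distraction & is.na(labels)
  labels[excl] <- "excluded"
  pre <- is.na(labels) & series$index <= bp
  labels[pre] <- "pre_stable"

  # Tukey upper fence; with IQR = 0 it collapses to Q3 and the strict
  # comparison yields no outliers among identical values
  fence <- function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] + fence_k * (q[2] - q[1])
  }
  post_idx <- which(is.na(labels))
  if (fence_scope == "pooled_z" && length(post_idx)) {
    route_z <- function(v) {
      stats::ave(v, series$route_label[post_idx], FUN = function(x)
        if (length(x) > 1 && sd(x) > 0) (x - mean(x)) / sd(x) else x - mean(x))
    }
    zt <- route_z(series$duration_s[post_idx])
    zu <- route_z(series$units[post_idx])
    out_t <- zt > fence(zt)
    out_u <- zu > fence(zu)
    is_err <- if (outlier_rule == "or") out_t | out_u else out_t & out_u
    labels[post_idx[is_err]] <- "error"
    labels[post_idx[!is_err]] <- "hit"
  }
  for (route in unique(series$route_label[post_idx])) {
    ridx <- post_idx[series$route_label[post_idx] == route]
    if (fence_scope == "per_route") {
      if (length(ridx) < min_route_n) {
        warning(sprintf("route %s: only %d post-breakpoint retrievals; quartiles undefined, no outliers flagged",
                        route, length(ridx)))
        labels[ridx] <- "hit"
        next
      }
      out_t <- series$duration_s[ridx] > fence(series$duration_s[ridx])
      out_u <- series$units[ridx] > fence(series$units[ridx])
      is_err <- if (outlier_rule == "or") out_t | out_u else out_t & out_u
      labels[ridx[is_err]] <- "error"
      labels[ridx[!is_err]] <- "hit"
    }
    hits <- ridx[labels[ridx] == "hit"]
    if (length(hits)) {
      min_u <- series$units[hits] == min(series$units[hits])
      min_t <- series$duration_s[hits] == min(series$duration_s[hits])
      best <- if (best_hit_rule == "both") min_u & min_t else min_u | min_t
      labels[hits[best]] <- "best_hit"
    }
  }
  structure(list(labels = labels, counts = table(labels), breakpoint = bp),
            class = "labeled_series")
}

#' Partition the post-breakpoint session into equal temporal intervals
#'
#' Splits the session time from the breakpoint retrieval's start to the
#' session end into `k` equal, contiguous, half-open intervals and assigns
#' each retrieval starting at or after the breakpoint time to its interval.
#'
#' @param series a `retrieval_series`.
#' @param breakpoint a `breakpoint_result` or retrieval index.
#' @param k number of intervals (2 = halves, 4 = quartiles).
#' @param t_start,t_end optional anchor and end times (s); defaults to the
#'   breakpoint retrieval's start time and the session end. Supplying them
#'   allows partitioning a control session on the clock of a matched
#'   wayfinding session.
#' @return list of class `interval_partition`: `k`, `boundaries` (length
#'   k+1), `assignment` (integer per retrieval; NA before the breakpoint).
#' @export
partition_intervals <- function(series, breakpoint, k = 2L,
                                t_start = NULL, t_end = NULL) {
  stopifnot(k %in% c(2L, 4L))
  bp <- if (inherits(breakpoint, "breakpoint_result")) breakpoint$chosen else as.integer(breakpoint)
  n <- nrow(series)
  bp_time <- t_start %||% series$start_time_s[bp]
  session_end <- t_end %||% (series$start_time_s[n] + series$duration_s[n])
  if (bp_time >= session_end)
    stop_localwake("breakpoint time must precede the session end", "localwake_domain_error")
  boundaries <- seq(bp_time, session_end, length.out = k + 1)
  assignment <- rep(NA_integer_, n)
  post <- series$start_time_s >= bp_time
  idx <- findInterval(series$start_time_s[post], boundaries,
                      rightmost.closed = TRUE, left.open = FALSE)
  assignment[post] <- pmin(idx, k)
  structure(list(k = k, boundaries = boundaries, assignment = assignment),
            class = "interval_partition")
}

#' Write / read a retrieval series as CSV
#'
#' One row per retrieval, with the columns of the `retrieval_series` layout.
#'
#' @param series a `retrieval_series`.
#' @param path file path.
#' @return `read_retrieval_csv` returns a `retrieval_series`.
#' @export
write_retrieval_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_retrieval_csv
#' @export
read_retrieval_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("index", "route_label", "x1", "z1", "x2", "z2",
              "start_time_s", "duration_s", "units", "distraction")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_localwake(paste("missing columns:", paste(missing, collapse = ", ")),
                   "localwake_format_error")
  if (any(df$duration_s <= 0))
    stop_localwake("durations must be positive", "localwake_format_error")
  class(df) <- c("retrieval_series", "data.frame")
  df
}
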