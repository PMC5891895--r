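#' Pipeline configuration
#'
#' Configuration of the end-to-end synthetic analysis: a wayfinding cohort
#' and a control cohort are generated, each subject's recording is analyzed
#' (breakpoint, labels, band power, delta waves), and group-level statistics
#' (error/hit comparisons, cluster permutation test, path model) are
#' computed.
#'
#' Between-subject heterogeneity induces the correlations the path model
#' estimates: a latent error-proneness factor scales each subject's error
#' probabilities, first-error latency and delta-wave susceptibility, and a
#' latent learning factor scales the pre-stabilization path-length excess.
#'
#' @param n_subjects wayfinding cohort size (>= 10 for the path model).
#' @param n_control control cohort size.
#' @param seed master seed; all per-subject seeds derive from it.
#' @param behavior named list of [behavior_sim_config()] overrides.
#' @param eeg named list of [eeg_sim_config()] overrides.
#' @param subject_sd sd (log scale) of the latent subject factors.
#' @param n_perm permutations for the cluster test.
#' @param k_intervals temporal intervals for the error/hit analysis.
#' @param bands band definitions, as [spectral_bands()].
#' @param outdir optional output directory for per-stage tables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 12L, n_control = 6L, seed = 1L,
                            behavior = list(n_retrievals = 150L,
                                            true_breakpoint_index = 40L),
                            eeg = list(),
                            subject_sd = 0.35,
                            n_perm = 500L, k_intervals = 2L,
                            bands = spectral_bands(),
                            outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# analyze one subject end to end; returns NULL when the pipeline must skip
# the subject (no stabilization / no errors are handled by the caller)
analyze_subject <- function(series, truth, recording, cfg) {
  bp <- find_breakpoint(series)
  labels <- suppressWarnings(classify_retrievals(series, bp))
  halves <- partition_intervals(series, bp, k = 2L)
  quart <- partition_intervals(series, bp, k = 4L)

  prep <- preprocess_eeg(recording, min_good_channels = 2L)
  bp_tab <- condition_band_power(prep, series, labels, halves, bands = cfg$bands)
  quart_tab <- condition_band_power(prep, series, labels = NULL, quart,
                                    bands = cfg$bands, by_label = FALSE)

  waves_rec <- lowpass_4hz(rereference_mastoids(prep))
  events <- detect_half_waves(waves_rec)
  durs <- setNames(series$duration_s, series$index)
  events <- suppressWarnings(threshold_top20(events, durs))
  regions <- truth$eeg_config$montage$regions
  wave_sum <- summarize_by_region(events, regions, series, labels)

  list(breakpoint = bp, labels = labels, halves = halves, quartiles = quart,
       band_power = bp_tab, quartile_power = quart_tab,
       wave_summary = wave_sum, events = events, series = series,
       truth = truth)
}

subject_config <- function(cfg, seed, err1_mult = 1, err2_mult = 1,
                           learn_mult = 1, delta_mult = 1, drift = NULL,
                           trend = TRUE) {
  b_over <- cfg$behavior
  b_over$seed <- seed
  base <- do.call(behavior_sim_config, b_over)
  base$error_prob_first_half <- min(0.45, base$error_prob_first_half * err1_mult)
  base$error_prob_second_half <- min(0.6, max(base$error_prob_first_half,
    base$error_prob_second_half * err2_mult))
  base$baseline_excess <- base$stable_excess +
    (base$baseline_excess - base$stable_excess) * learn_mult
  if (!trend) {
    # control task: no learning trend and a low, time-constant error rate
    base$baseline_duration_mean <- base$stable_duration_mean
    base$baseline_duration_sd <- base$stable_duration_sd
    base$baseline_excess <- base$stable_excess
    base$ramp_fraction <- 0
    base$error_prob_first_half <- 0.03
    base$error_prob_second_half <- 0.03
  }
  e_over <- cfg$eeg
  e_over$seed <- seed + 1L
  eeg <- do.call(eeg_sim_config, e_over)
  eeg$delta_wave_rate_hit <- eeg$delta_wave_rate_hit * delta_mult
  eeg$delta_wave_rate_error <- eeg$delta_wave_rate_error * delta_mult
  if (!is.null(drift)) eeg$rate_drift_per_min <- drift
  list(behavior = base, eeg = eeg)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Generates the two cohorts, analyzes every subject, and assembles the
#' group-level report: error/hit counts by temporal half, delta-wave
#' error-versus-hit comparisons (count and amplitude, one-tailed paired t
#' with effect sizes), a cluster permutation test of second-half error delta
#' power against baseline, the quartile time course of delta power in both
#' cohorts, and the fitted path model. Subjects without a detectable
#' breakpoint or without errors are skipped with a message (the path model
#' requires complete subjects).
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_report` (see fields in the description);
#'   when `cfg$outdir` is set, per-stage tables and a manifest are written
#'   there as TSV/CSV/JSON.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  set.seed(cfg$seed)
  n_w <- cfg$n_subjects
  # latent chain: stronger learners saturate later and are more susceptible
  # to use-dependent delta waves, which in turn raise second-half errors
  lat_learn <- exp(rnorm(n_w, 0, cfg$subject_sd))
  lat_delta <- lat_learn^0.8 * exp(rnorm(n_w, 0, cfg$subject_sd / 2))
  seeds <- sample.int(2^20, n_w + cfg$n_control)

  subjects <- vector("list", n_w)
  for (s in seq_len(n_w)) {
    sc <- subject_config(cfg, seeds[s],
                         err1_mult = 1 / lat_learn[s],
                         err2_mult = lat_delta[s]^0.8,
                         learn_mult = lat_learn[s], delta_mult = lat_delta[s])
    beh <- gen_behavior(sc$behavior)
    ee <- gen_eeg(sc$eeg, beh$series, beh$truth)
    subjects[[s]] <- tryCatch(
      analyze_subject(beh$series, ee$truth, ee$recording, cfg),
      localwake_error = function(e) {
        message("subject ", s, " skipped: ", conditionMessage(e)); NULL
      })
  }
  ok <- !vapply(subjects, is.null, logical(1))
  subjects <- subjects[ok]

  # ---- group behavioral statistics: errors and best hits by half ----
  half_counts <- function(sub, what) {
    iv <- sub$halves$assignment
    lab <- sub$labels$labels
    vapply(1:2, function(h) sum(lab == what & !is.na(iv) & iv == h, na.rm = TRUE),
           numeric(1))
  }
  err_by_half <- t(vapply(subjects, half_counts, numeric(2), what = "error"))
  bh_by_half <- t(vapply(subjects, half_counts, numeric(2), what = "best_hit"))
  t_err <- paired_t_one_tailed(err_by_half[, 2], err_by_half[, 1], "greater")
  t_bh <- tryCatch(paired_t_one_tailed(bh_by_half[, 2], bh_by_half[, 1], "greater"),
                   localwake_degenerate = function(e) NULL)

  # ---- delta waves: errors versus hits over the regions ----
  wave_tab <- do.call(rbind, lapply(seq_along(subjects), function(i)
    cbind(subject = i, subjects[[i]]$wave_summary)))
  per_subj <- function(cond, col) vapply(seq_along(subjects), function(i) {
    w <- subjects[[i]]$wave_summary
    mean(w[[col]][w$condition == cond], na.rm = TRUE)
  }, numeric(1))
  n_err <- per_subj("error", "n_waves_per_min")
  n_hit <- per_subj("hit", "n_waves_per_min")
  a_err <- per_subj("error", "mean_amp")
  a_hit <- per_subj("hit", "mean_amp")
  cmp_ok <- is.finite(n_err) & is.finite(n_hit) & is.finite(a_err) & is.finite(a_hit)
  t_wave_n <- paired_t_one_tailed(n_err[cmp_ok], n_hit[cmp_ok], "greater")
  t_wave_a <- paired_t_one_tailed(a_err[cmp_ok], a_hit[cmp_ok], "less")

  # ---- cluster test: second-half error delta power vs baseline ----
  get_power <- function(sub, cond) {
    t <- sub$band_power
    v <- t$log_power[t$band == "delta" & t$condition == cond]
    names(v) <- t$channel[t$band == "delta" & t$condition == cond]
    v
  }
  chans <- sort(unique(subjects[[1]]$band_power$channel))
  mat_of <- function(cond) {
    rows <- lapply(subjects, function(sub) get_power(sub, cond)[chans])
    do.call(rbind, rows)
  }
  m_err2 <- mat_of("errors_2")
  m_base <- mat_of("baseline")
  keep_s <- stats::complete.cases(m_err2) & stats::complete.cases(m_base)
  cluster <- NULL
  if (sum(keep_s) >= 5) {
    first_ok <- which(keep_s)[1]
    pos <- subjects[[first_ok]]$truth$eeg_config$montage$positions[chans, , drop = FALSE]
    adj <- build_adjacency(pos)
    cluster <- cluster_permutation_test(m_err2[keep_s, , drop = FALSE],
                                        m_base[keep_s, , drop = FALSE],
                                        adj, n_perm = cfg$n_perm,
                                        seed = cfg$seed + 7L)
  }

  # ---- quartile delta time course, wayfinding ----
  q_power <- function(sub) vapply(1:4, function(q) {
    t <- sub$quartile_power
    mean(t$log_power[t$band == "delta" & t$condition == paste0("interval_", q)])
  }, numeric(1))
  way_quart <- t(vapply(subjects, q_power, numeric(4)))

  # ---- control cohort: flat behavior, no rate drift ----
  mean_bp_time <- mean(vapply(subjects, function(s) s$breakpoint$chosen_time_s, numeric(1)))
  mean_base_end <- mean(vapply(subjects, function(s) s$series$start_time_s[17], numeric(1)))
  ctrl_quart <- NULL
  if (cfg$n_control > 0) {
    ctrl_quart <- matrix(NA_real_, cfg$n_control, 4)
    for (s in seq_len(cfg$n_control)) {
      sc <- subject_config(cfg, seeds[n_w + s], drift = 0, trend = FALSE)
      beh <- gen_behavior(sc$behavior)
      ee <- gen_eeg(sc$eeg, beh$series, beh$truth)
      prep <- preprocess_eeg(ee$recording, min_good_channels = 2L)
      part <- partition_intervals(beh$series, 1L, k = 4L,
                                  t_start = min(mean_bp_time,
                                                0.9 * ee$recording$duration_s))
      qt <- condition_band_power(prep, beh$series, labels = NULL, part,
                                 bands = cfg$bands, by_label = FALSE,
                                 baseline_clock = c(0, mean_base_end))
      ctrl_quart[s, ] <- vapply(1:4, function(q)
        mean(qt$log_power[qt$band == "delta" & qt$condition == paste0("interval_", q)]),
        numeric(1))
    }
  }

  # ---- path model over complete subjects ----
  path_rows <- lapply(seq_along(subjects), function(i) {
    sub <- subjects[[i]]
    imp <- tryCatch(suppressWarnings(build_improvement(sub$series, sub$labels)),
                    localwake_error = function(e) NULL)
    if (is.null(imp)) return(NULL)
    regions <- sub$truth$eeg_config$montage$regions
    t <- sub$band_power
    ls_chan <- t$band == "delta" & t$condition == "errors_2" &
      t$channel %in% unlist(regions)
    if (!any(ls_chan)) return(NULL)
    iv <- sub$halves$assignment
    data.frame(subject = i,
               improvement = imp$improvement,
               saturation = imp$first_error_time_s,
               local_sleep = mean(t$log_power[ls_chan]),
               errors = sum(sub$labels$labels == "error" & !is.na(iv) & iv == 2))
  })
  path_data <- do.call(rbind, path_rows[!vapply(path_rows, is.null, logical(1))])
  path_fit <- NULL
  if (!is.null(path_data) && nrow(path_data) >= 10)
    path_fit <- tryCatch(fit_path_model(path_data),
                         localwake_error = function(e) NULL)

  report <- structure(list(
    n_subjects_analyzed = length(subjects),
    err_by_half = err_by_half, best_hits_by_half = bh_by_half,
    t_errors_half2_gt_half1 = t_err, t_best_hits_half2_gt_half1 = t_bh,
    wave_summary = wave_tab,
    waves_per_min = data.frame(error = n_err, hit = n_hit),
    wave_amp = data.frame(error = a_err, hit = a_hit),
    t_wave_count = t_wave_n, t_wave_amp = t_wave_a,
    cluster_errors2_vs_baseline = cluster,
    wayfinding_quartile_delta = way_quart,
    control_quartile_delta = ctrl_quart,
    path_data = path_data, path_fit = path_fit,
    config = cfg
  ), class = "pipeline_report")

  if (!is.null(cfg$outdir)) write_pipeline_report(report, cfg$outdir)
  report
}

#' Write the per-stage tables of a pipeline report
#'
#' @param report a `pipeline_report`.
#' @param outdir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_pipeline_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(report$wave_summary, "wave_summary.tsv")
  wt(data.frame(subject = seq_len(nrow(report$err_by_half)),
                errors_half1 = report$err_by_half[, 1],
                errors_half2 = report$err_by_half[, 2]), "errors_by_half.tsv")
  if (!is.null(report$path_data))
    utils::write.csv(report$path_data, file.path(outdir, "path_data.csv"),
                     row.names = FALSE)
  js <- list(
    t_errors = unclass(report$t_errors_half2_gt_half1),
    t_wave_count = unclass(report$t_wave_count),
    t_wave_amp = unclass(report$t_wave_amp),
    path_fit = if (!is.null(report$path_fit)) unclass(report$path_fit),
    cluster = if (!is.null(report$cluster_errors2_vs_baseline)) {
      cl <- report$cluster_errors2_vs_baseline
      list(n_clusters = length(cl$clusters),
           clusters = lapply(cl$clusters, function(c)
             list(channels = c$channels, sum_t = c$sum_t, p = c$p)))
    },
    wayfinding_quartile_delta = colMeans(report$wayfinding_quartile_delta),
    control_quartile_delta = if (!is.null(report$control_quartile_delta))
      colMeans(report$control_quartile_delta)
  )
  jsonlite::write_json(js, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package = "localwake",
    version = as.character(utils::packageVersion("localwake")),
    r_version = R.version.string,
    seed = report$config$seed,
    n_subjects = report$config$n_subjects,
    n_control = report$config$n_control,
    n_perm = report$config$n_perm,
    behavior_overrides = report$config$behavior,
    eeg_overrides = report$config$eeg,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Serialize a recording's metadata and annotations as a JSON sidecar
#'
#' The samples themselves are regenerated from seeds rather than stored;
#' this sidecar carries everything needed to interpret a recording: channel
#' labels and positions, sampling rate, annotations, and (optionally) the
#' injected ground-truth events.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @param truth optional ground-truth list from [gen_eeg()].
#' @return the path, invisibly.
#' @export
write_recording_sidecar <- function(rec, path, truth = NULL) {
  side <- list(
    channel_labels = rec$channel_labels,
    positions = apply(rec$positions, 1, function(p) as.list(setNames(p, c("x", "y", "z"))),
                      simplify = FALSE),
    fs_hz = rec$fs_hz,
    duration_s = rec$duration_s,
    annotations = rec$annotations,
    injected_events = if (!is.null(truth)) truth$injected_events
  )
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
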