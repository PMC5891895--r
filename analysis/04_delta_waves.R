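#!/usr/bin/env Rscript
# Stage 4: individual delta half-waves.
#
# Mastoid re-reference, zero-phase 4 Hz Chebyshev-II low-pass, negative
# half-wave detection (0.125-0.5 s duration gate), top-20 % amplitude
# thresholding per subject and channel (reciprocal-duration weighting), and
# region x condition summaries. Group test: are delta waves more frequent
# and larger (more negative) during errors than hits?

source("analysis/00_common.R")
out <- "results"
cohort <- load_cohort(out)

summ <- list()
for (id in way_ids(cohort)) {
  sub <- regen_subject(id, cohort)
  series <- sub$series
  bp <- tryCatch(find_breakpoint(series), localwake_no_stabilization = function(e) NULL)
  if (is.null(bp)) next
  lab <- suppressWarnings(classify_retrievals(series, bp))
  prep <- preprocess_eeg(sub$recording, min_good_channels = 2L)
  wrec <- lowpass_4hz(rereference_mastoids(prep))
  ev <- detect_half_waves(wrec)
  ev <- suppressWarnings(threshold_top20(ev, setNames(series$duration_s, series$index)))
  regions <- default_montage(8)$regions
  ws <- summarize_by_region(ev, regions, series, lab)
  summ[[id]] <- cbind(subject = id, ws)
}
wave_tab <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
write_tsv(wave_tab, file.path(out, "wave_summary.tsv"))

per_subject <- function(cond, col) vapply(unique(wave_tab$subject), function(s) {
  w <- wave_tab[wave_tab$subject == s & wave_tab$condition == cond, ]
  mean(w[[col]], na.rm = TRUE)
}, numeric(1))
n_err <- per_subject("error", "n_waves_per_min")
n_hit <- per_subject("hit", "n_waves_per_min")
a_err <- per_subject("error", "mean_amp")
a_hit <- per_subject("hit", "mean_amp")
ok <- is.finite(n_err) & is.finite(n_hit) & is.finite(a_err) & is.finite(a_hit)

t_n <- paired_t_one_tailed(n_err[ok], n_hit[ok], "greater")
t_a <- paired_t_one_tailed(a_err[ok], a_hit[ok], "less")
cat(sprintf("delta waves/min: errors %.2f vs hits %.2f; t(%d) = %.2f, p = %.4g, d = %.2f\n",
            mean(n_err[ok]), mean(n_hit[ok]), t_n$df, t_n$statistic, t_n$p,
            t_n$effect_size))
cat(sprintf("negative peak uV: errors %.1f vs hits %.1f; t(%d) = %.2f, p = %.4g, d = %.2f\n",
            mean(a_err[ok]), mean(a_hit[ok]), t_a$df, t_a$statistic, t_a$p,
            t_a$effect_size))
cat("wave_summary.tsv written\n")
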