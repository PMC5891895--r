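#!/usr/bin/env Rscript
# Stage 3: condition-wise band power.
#
# Regenerates each subject's EEG from its stored seed, preprocesses it
# (0.5-45 Hz zero-phase band-pass, decimation to 125 Hz, average reference),
# and computes log delta / theta Welch band power per channel for (a)
# errors/hits in the two breakpoint-anchored halves plus the 16-retrieval
# baseline and (b) the four breakpoint-anchored quartiles (all retrievals
# pooled), for both cohorts. The control quartiles are anchored at the
# wayfinding cohort's mean breakpoint time with a clock-matched baseline.

source("analysis/00_common.R")
out <- "results"
cohort <- load_cohort(out)

power_rows <- list(); quart_rows <- list()
bp_times <- c(); base_ends <- c()

for (id in way_ids(cohort)) {
  sub <- regen_subject(id, cohort)
  series <- sub$series
  bp <- tryCatch(find_breakpoint(series), localwake_no_stabilization = function(e) NULL)
  if (is.null(bp)) next
  lab <- suppressWarnings(classify_retrievals(series, bp))
  prep <- preprocess_eeg(sub$recording, min_good_channels = 2L)
  halves <- partition_intervals(series, bp, k = 2L)
  quart <- partition_intervals(series, bp, k = 4L)
  tab <- condition_band_power(prep, series, lab, halves)
  qt <- condition_band_power(prep, series, labels = NULL, quart, by_label = FALSE)
  power_rows[[id]] <- cbind(subject = id, tab)
  quart_rows[[id]] <- cbind(subject = id, task = "wayfinding", qt)
  bp_times <- c(bp_times, bp$chosen_time_s)
  base_ends <- c(base_ends, series$start_time_s[17])
}

anchor <- mean(bp_times); base_end <- mean(base_ends)
for (id in ctl_ids(cohort)) {
  sub <- regen_subject(id, cohort)
  prep <- preprocess_eeg(sub$recording, min_good_channels = 2L)
  part <- partition_intervals(sub$series, 1L, k = 4L,
                              t_start = min(anchor, 0.9 * sub$recording$duration_s))
  qt <- condition_band_power(prep, sub$series, labels = NULL, part,
                             by_label = FALSE, baseline_clock = c(0, base_end))
  quart_rows[[id]] <- cbind(subject = id, task = "control", qt)
}

power_tab <- do.call(rbind, c(power_rows, list(make.row.names = FALSE)))
quart_tab <- do.call(rbind, c(quart_rows, list(make.row.names = FALSE)))
write_tsv(power_tab, file.path(out, "band_power.tsv"))
write_tsv(quart_tab, file.path(out, "quartile_power.tsv"))

qmean <- function(task, q) {
  sel <- quart_tab$task == task & quart_tab$band == "delta" &
    quart_tab$condition == paste0("interval_", q)
  mean(quart_tab$log_power[sel])
}
cat("mean log delta power by quartile (wayfinding):",
    sprintf("%.3f", vapply(1:4, qmean, numeric(1), task = "wayfinding")), "\n")
cat("mean log delta power by quartile (control):   ",
    sprintf("%.3f", vapply(1:4, qmean, numeric(1), task = "control")), "\n")
cat("band_power.tsv and quartile_power.tsv written\n")
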