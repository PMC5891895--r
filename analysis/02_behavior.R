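#!/usr/bin/env Rscript
# Stage 2: behavioral analysis.
#
# For every wayfinding subject: detect the performance breakpoint on the
# standardized duration and path-unit series, classify retrievals (baseline /
# pre-stable / hit / best hit / error / excluded), split the post-breakpoint
# session into temporal halves, and test whether errors and best hits
# increase in the second half (one-tailed paired t with Cohen's d).

source("analysis/00_common.R")
out <- "results"
cohort <- load_cohort(out)
dir.create(file.path(out, "labels"), showWarnings = FALSE)

rows <- list(); halves <- list()
for (id in way_ids(cohort)) {
  sub <- regen_subject(id, cohort, with_eeg = FALSE)
  series <- read_retrieval_csv(file.path(out, "behavior", paste0(id, ".csv")))
  bp <- tryCatch(find_breakpoint(series), localwake_no_stabilization = function(e) NULL)
  if (is.null(bp)) { message(id, ": no stabilization, skipped"); next }
  lab <- suppressWarnings(classify_retrievals(series, bp))
  part <- partition_intervals(series, bp, k = 2L)
  write_tsv(data.frame(index = series$index, label = lab$labels,
                       interval = part$assignment),
            file.path(out, "labels", paste0(id, ".tsv")))
  truth_bp <- sub$truth$true_breakpoint
  rows[[id]] <- data.frame(
    subject = id,
    bp_time_series = bp$bp_time_series, bp_units_series = bp$bp_units_series,
    chosen = bp$chosen, chosen_time_min = bp$chosen_time_s / 60,
    true_breakpoint = truth_bp,
    n_errors = sum(lab$labels == "error"),
    n_best_hits = sum(lab$labels == "best_hit"))
  cnt <- function(what, h) sum(lab$labels == what & !is.na(part$assignment) &
                                 part$assignment == h)
  halves[[id]] <- data.frame(subject = id,
                             errors_1 = cnt("error", 1), errors_2 = cnt("error", 2),
                             best_hits_1 = cnt("best_hit", 1),
                             best_hits_2 = cnt("best_hit", 2))
}
bp_tab <- do.call(rbind, rows)
half_tab <- do.call(rbind, halves)
write_tsv(bp_tab, file.path(out, "breakpoints.tsv"))
write_tsv(half_tab, file.path(out, "errors_by_half.tsv"))

t_err <- paired_t_one_tailed(half_tab$errors_2, half_tab$errors_1, "greater")
t_bh <- paired_t_one_tailed(half_tab$best_hits_2, half_tab$best_hits_1, "greater")

cat(sprintf("breakpoint: mean %.1f min (retrieval %.1f); ground truth index %.1f\n",
            mean(bp_tab$chosen_time_min), mean(bp_tab$chosen),
            mean(bp_tab$true_breakpoint)))
cat(sprintf("errors rise in the second half: t(%d) = %.2f, p = %.4g, d = %.2f\n",
            t_err$df, t_err$statistic, t_err$p, t_err$effect_size))
cat(sprintf("best hits second vs first half: t(%d) = %.2f, p = %.4g, d = %.2f\n",
            t_bh$df, t_bh$statistic, t_bh$p, t_bh$effect_size))
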