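#!/usr/bin/env Rscript
# Stage 1: simulate the study cohorts.
#
# Generates a 12-subject wayfinding cohort and a 5-subject control cohort.
# Between-subject latent factors couple learning speed, first-error latency
# and delta-wave susceptibility, which is what the path model downstream is
# meant to recover. Behavioral series are written as CSV; EEG is regenerated
# downstream from the seeds stored in the cohort manifest (recordings are
# large and fully determined by their configuration).

suppressPackageStartupMessages(library(localwake))

out <- "results"
dir.create(file.path(out, "behavior"), recursive = TRUE, showWarnings = FALSE)

master_seed <- 20260926L
set.seed(master_seed)
n_way <- 12L
n_ctl <- 5L

lat_learn <- exp(rnorm(n_way, 0, 0.35))
lat_delta <- lat_learn^0.8 * exp(rnorm(n_way, 0, 0.175))
seeds <- sample.int(2^20, n_way + n_ctl)

subject_cfg <- function(i, control = FALSE) {
  beh <- list(n_retrievals = 100L, true_breakpoint_index = 30L,
              baseline_duration_mean = 30, stable_duration_mean = 14,
              seed = seeds[i])
  eeg <- list(seed = seeds[i] + 1L)
  if (control) {
    beh$baseline_duration_mean <- beh$stable_duration_mean
    beh$ramp_fraction <- 0
    beh$baseline_excess <- 0.10
    beh$error_prob_first_half <- 0.03
    beh$error_prob_second_half <- 0.03
    eeg$rate_drift_per_min <- 0
  } else {
    k <- i
    beh$error_prob_first_half <- min(0.45, 0.10 / lat_learn[k])
    beh$error_prob_second_half <- min(0.6, max(beh$error_prob_first_half,
                                               0.24 * lat_delta[k]^0.8))
    beh$baseline_excess <- 0.10 + (1.0 - 0.10) * lat_learn[k]
    eeg$delta_rate_mult <- lat_delta[k]
  }
  list(behavior = beh, eeg = eeg, control = control)
}

cohort <- c(lapply(seq_len(n_way), subject_cfg),
            lapply(n_way + seq_len(n_ctl), subject_cfg, control = TRUE))
names(cohort) <- c(sprintf("way%02d", seq_len(n_way)),
                   sprintf("ctl%02d", seq_len(n_ctl)))

for (id in names(cohort)) {
  cfg <- cohort[[id]]
  bcfg <- do.call(behavior_sim_config, cfg$behavior)
  beh <- gen_behavior(bcfg)
  write_retrieval_csv(beh$series, file.path(out, "behavior", paste0(id, ".csv")))
  cohort[[id]]$n_true_errors <- length(beh$truth$true_error_index)
}

jsonlite::write_json(list(master_seed = master_seed, subjects = cohort),
                     file.path(out, "cohort.json"),
                     auto_unbox = TRUE, digits = NA, null = "null")

n_err <- vapply(cohort[seq_len(n_way)], `[[`, numeric(1), "n_true_errors")
cat(sprintf("simulated %d wayfinding + %d control subjects\n", n_way, n_ctl))
cat(sprintf("ground-truth errors per wayfinding subject: mean %.1f (range %d-%d)\n",
            mean(n_err), min(n_err), max(n_err)))
cat("behavior CSVs and cohort manifest written under results/\n")
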