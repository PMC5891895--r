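# Shared helpers for the numbered analysis scripts: load the cohort manifest
# written by 01_simulate.R and regenerate a subject's data deterministically
# from its stored configuration.

suppressPackageStartupMessages(library(localwake))

load_cohort <- function(out = "results") {
  f <- file.path(out, "cohort.json")
  if (!file.exists(f)) stop("run analysis/01_simulate.R first: missing ", f)
  jsonlite::read_json(f, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

regen_subject <- function(id, cohort, with_eeg = TRUE) {
  cfg <- cohort$subjects[[id]]
  bcfg <- do.call(behavior_sim_config, cfg$behavior[
    setdiff(names(cfg$behavior), character(0))])
  beh <- gen_behavior(bcfg)
  if (!with_eeg) return(list(series = beh$series, truth = beh$truth, cfg = cfg))
  e_args <- cfg$eeg
  mult <- e_args$delta_rate_mult
  e_args$delta_rate_mult <- NULL
  ecfg <- do.call(eeg_sim_config, e_args)
  if (!is.null(mult)) {
    ecfg$delta_wave_rate_hit <- ecfg$delta_wave_rate_hit * mult
    ecfg$delta_wave_rate_error <- ecfg$delta_wave_rate_error * mult
  }
  ee <- gen_eeg(ecfg, beh$series, beh$truth)
  list(series = beh$series, truth = ee$truth, recording = ee$recording, cfg = cfg)
}

way_ids <- function(cohort) {
  names(cohort$subjects)[!vapply(cohort$subjects, `[[`, logical(1), "control")]
}
ctl_ids <- function(cohort) {
  names(cohort$subjects)[vapply(cohort$subjects, `[[`, logical(1), "control")]
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
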