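#!/usr/bin/env Rscript
# Stage 6: the learning-related use-dependent local sleep path model.
#
# Builds the four per-subject variables — repetition-dependent improvement
# (best-hit-weighted deviation rate before the first error), use-dependent
# saturation (clock time of the first error), local sleep in wake (mean
# regional log delta power of second-half errors), and the second-half error
# count — and fits the recursive three-regression model with ML fit indices.

source("analysis/00_common.R")
out <- "results"
cohort <- load_cohort(out)
power_tab <- utils::read.table(file.path(out, "band_power.tsv"),
                               header = TRUE, sep = "\t")
regions <- unlist(default_montage(8)$regions)

rows <- list()
for (id in way_ids(cohort)) {
  series <- read_retrieval_csv(file.path(out, "behavior", paste0(id, ".csv")))
  labf <- file.path(out, "labels", paste0(id, ".tsv"))
  if (!file.exists(labf)) next
  ltab <- utils::read.table(labf, header = TRUE, sep = "\t")
  lab <- structure(list(labels = ltab$label, counts = table(ltab$label),
                        breakpoint = NA_integer_), class = "labeled_series")
  imp <- tryCatch(suppressWarnings(build_improvement(series, lab)),
                  localwake_error = function(e) NULL)
  if (is.null(imp)) { message(id, ": no usable improvement value"); next }
  sel <- power_tab$subject == id & power_tab$band == "delta" &
    power_tab$condition == "errors_2" & power_tab$channel %in% regions
  if (!any(sel)) { message(id, ": no second-half error spectra"); next }
  rows[[id]] <- data.frame(
    subject = id,
    improvement = imp$improvement,
    saturation = imp$first_error_time_s,
    local_sleep = mean(power_tab$log_power[sel]),
    errors = sum(ltab$label == "error" & !is.na(ltab$interval) & ltab$interval == 2))
}
path_data <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
utils::write.csv(path_data, file.path(out, "path_data.csv"), row.names = FALSE)

fit <- fit_path_model(path_data)
print(fit)
jsonlite::write_json(
  list(betas = as.list(fit$betas), se = fit$se, p = fit$p,
       chi2 = fit$chi2, df = fit$df, p_chi2 = fit$p_chi2,
       srmr = fit$srmr, rmsea = fit$rmsea, cfi = fit$cfi,
       aic_model = fit$aic_model, aic_saturated = fit$aic_saturated,
       n = fit$n),
  file.path(out, "path_fit.json"), auto_unbox = TRUE, digits = NA)
cat("path_data.csv and path_fit.json written\n")
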