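#!/usr/bin/env Rscript
# Stage 5: topographic cluster statistics.
#
# Paired cluster-based permutation tests on the per-channel log delta power
# tables from stage 3: second-half errors vs baseline and second-half hits
# vs baseline, with channel adjacency derived from sensor positions and the
# max-cluster-mass Monte-Carlo correction.

source("analysis/00_common.R")
out <- "results"
cohort <- load_cohort(out)
power_tab <- utils::read.table(file.path(out, "band_power.tsv"),
                               header = TRUE, sep = "\t")

chans <- sort(unique(power_tab$channel))
mat_of <- function(cond) {
  subs <- sort(unique(power_tab$subject))
  m <- t(vapply(subs, function(s) {
    sel <- power_tab$subject == s & power_tab$band == "delta" &
      power_tab$condition == cond
    v <- setNames(power_tab$log_power[sel], power_tab$channel[sel])
    unname(v[chans])
  }, numeric(length(chans))))
  rownames(m) <- subs
  m
}

mont <- default_montage(8)
adj <- build_adjacency(mont$positions[chans, , drop = FALSE])
res <- list()
for (cond in c("errors_2", "hits_2")) {
  a <- mat_of(cond); b <- mat_of("baseline")
  keep <- stats::complete.cases(a) & stats::complete.cases(b)
  r <- cluster_permutation_test(a[keep, , drop = FALSE], b[keep, , drop = FALSE],
                                adj, n_perm = 1000, seed = 105)
  res[[cond]] <- list(
    n_subjects = sum(keep),
    clusters = lapply(r$clusters, function(cl)
      list(channels = chans[cl$channels], sum_t = cl$sum_t, p = cl$p)),
    significant_channels = chans[r$sig_mask])
  cat(sprintf("%s vs baseline (delta, n = %d): %d cluster(s)\n",
              cond, sum(keep), length(r$clusters)))
  for (cl in r$clusters)
    cat(sprintf("  %s: sum t = %.1f, p = %.4f\n",
                paste(chans[cl$channels], collapse = ","), cl$sum_t, cl$p))
}
jsonlite::write_json(res, file.path(out, "cluster.json"),
                     auto_unbox = TRUE, digits = NA)
cat("cluster.json written\n")
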