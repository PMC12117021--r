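#!/usr/bin/env Rscript
# Experiment 1: lesion-network symptom mapping. Seeds the normative
# connectome with each lesion, masks the averaged Fisher-z maps to the
# cortical shell, and tests the association with neglect severity — the
# frequentist GLM with max-statistic permutation FWE, and the Bayes-factor
# map with conventional evidence bins — for the whole cohort and per
# lesion group. Writes a JSON summary and the per-group bin fractions.

library(neglectdisc)

cohort <- read_cohort(file.path("results", "cohort"))
cfg <- run_config(n_perm_voxel = 500, seed = 20251001L)

message("Building lesion-network maps and mapping severity ...")
res <- run_experiment1(cohort, cfg)

for (g in names(res$groups)) {
  r <- res$groups[[g]]
  if (!is.null(r$skipped)) {
    message(sprintf("[%s] skipped: %s", g, r$skipped))
    next
  }
  message(sprintf(
    "[%s] n = %d, %d cortical voxels tested; FWE threshold |t| = %.2f; %d significant voxel(s)",
    g, r$n_patients, r$n_voxels_tested, r$stat$fwe_threshold,
    sum(r$stat$sig_mask)))
  if (!is.null(r$bf)) {
    bp <- r$bf$bin_proportions
    message(sprintf(
      "[%s] Bayes bins: %.1f%% anecdotal H0, %.1f%% anecdotal H1, %.1f%% moderate+ H1",
      g, 100 * bp[["h0_anecdotal"]], 100 * bp[["h1_anecdotal"]],
      100 * sum(bp[c("h1_moderate", "h1_strong", "h1_very_strong")])))
  }
}

dir.create(file.path("results", "experiment1"), recursive = TRUE,
           showWarnings = FALSE)
summary <- lapply(res$groups, function(r) {
  if (!is.null(r$skipped)) return(list(skipped = r$skipped))
  out <- list(n_patients = r$n_patients,
              n_voxels_tested = r$n_voxels_tested,
              fwe_threshold = r$stat$fwe_threshold,
              n_significant = sum(r$stat$sig_mask))
  if (!is.null(r$bf)) out$bf_bin_proportions <- as.list(r$bf$bin_proportions)
  out
})
jsonlite::write_json(summary,
                     file.path("results", "experiment1", "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Summary written to results/experiment1/summary.json")
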