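#!/usr/bin/env Rscript
# Experiment 3: tract-wise lesion load. Binary (p >= 0.3) and
# probability-weighted loads for SLF, IOF, SOF and UF; Kendall rank
# correlations with severity (per tract with Bonferroni correction, and
# for the total load), the presence chi-square (any load vs none, by
# neglect status), and the random-forest classification of the binary
# neglect label with a permutation test of the cross-validated AUC.

library(neglectdisc)

cohort <- read_cohort(file.path("results", "cohort"),
                      with_connectome = FALSE)
cfg <- run_config(classifier = classifier_config(n_splits = 100,
                                                 n_perm = 500),
                  seed = 20251001L)

message("Computing lesion loads and association statistics ...")
res <- run_experiment3(cohort, cfg)

dir.create(file.path("results", "experiment3"), recursive = TRUE,
           showWarnings = FALSE)
utils::write.csv(cbind(patient_id = cohort$behaviour$patient_id,
                       res$loads_binary),
                 file.path("results", "experiment3", "loads_binary.csv"),
                 row.names = FALSE)
utils::write.csv(cbind(patient_id = cohort$behaviour$patient_id,
                       res$loads_weighted),
                 file.path("results", "experiment3", "loads_weighted.csv"),
                 row.names = FALSE)

for (g in names(res$association)) {
  a <- res$association[[g]]
  if (!is.null(a$skipped)) {
    message(sprintf("[%s] skipped: %s", g, a$skipped))
    next
  }
  message(sprintf("[%s] n = %d", g, a$n_patients))
  print(a$binary$per_tract, digits = 3)
  message(sprintf(
    "[%s] total load: tau = %.3f (p = %.4f binary); tau = %.3f (p = %.4f weighted)",
    g, a$binary$total$tau, a$binary$total$p,
    a$weighted$total$tau, a$weighted$total$p))
  if (!is.null(a$binary$presence))
    message(sprintf("[%s] presence chi-square(1, N = %d) = %.2f, p = %.3f",
                    g, sum(a$binary$presence$table),
                    a$binary$presence$chi2, a$binary$presence$p))
}

if (is.null(res$classifier$skipped)) {
  message(sprintf(
    "Random forest: mean test AUC = %.3f over %d splits; permutation p = %.4f (%d permutations)",
    res$classifier$mean_auc, res$classifier$config$n_splits,
    res$classifier$p_value, res$classifier$config$n_perm))
} else message("Classifier skipped: ", res$classifier$skipped)

summary <- list(
  association = lapply(res$association, function(a) {
    if (!is.null(a$skipped)) return(list(skipped = a$skipped))
    list(n_patients = a$n_patients,
         per_tract_binary = a$binary$per_tract,
         total_binary = a$binary$total,
         total_weighted = a$weighted$total,
         presence = if (is.null(a$binary$presence)) NULL else
           list(chi2 = a$binary$presence$chi2, p = a$binary$presence$p,
                table = a$binary$presence$table))
  }),
  classifier = if (is.null(res$classifier$skipped))
    list(mean_auc = res$classifier$mean_auc,
         p_value = res$classifier$p_value)
  else list(skipped = res$classifier$skipped))
jsonlite::write_json(summary,
                     file.path("results", "experiment3", "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Summary written to results/experiment3/summary.json")
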