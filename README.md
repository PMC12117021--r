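# neglectdisc

Spatial neglect — the attentional deviation toward the ipsilesional side
after (typically right-hemisphere) stroke — is usually attributed to
cortical damage, yet it also occurs after purely subcortical stroke of
the basal ganglia or thalamus. `neglectdisc` implements a three-part
analysis pipeline for asking *why*: is neglect after subcortical stroke
explained by disrupted subcortico-cortical connectivity, or by incidental
damage to the cortico-cortical association tracts (SLF, IOF, SOF, UF)
that run directly past these structures?

The package is aimed at lesion-behaviour researchers. From binary lesion
masks in template space, cancellation-test behaviour, and normative
reference data (resting-state fMRI time series, streamline sets,
probabilistic tract atlases) it computes:

1. **Lesion-network mapping** — each lesion seeds the normative rs-fMRI;
   per-voxel Pearson correlations are Fisher-transformed
   (`z = atanh(r)`), averaged across normative subjects, and masked to
   cortical grey matter. Severity associations are tested per voxel with
   the slope t statistic `t = r sqrt((n-2)/(1-r^2))` under
   maximum-statistic permutation FWE correction, and replicated as a
   Bayes-factor map (Cauchy prior on the standardised slope, scale
   `sqrt(2)/2`), binned by the usual evidence conventions
   (BF > 3 / 10 / 30).
2. **Streamline disconnection** — per patient, the set of normative
   streamlines intersecting the lesion (arc-length resampling at 0.5 mm);
   streamlines disconnected in ≥ 5 patients are tested one-tailed with a
   pooled-variance two-sample t and max-t permutation FWE, then counted
   per tract.
3. **Tract-wise lesion load** — damaged fraction of each tract after
   binarising its probabilistic map at p ≥ 0.3 (plus a
   probability-weighted variant); Kendall tau-b against severity with
   Bonferroni correction, a presence chi-square (any load × neglect), and
   a random-forest classifier (100 trees, depth 3, min split 5) of the
   binary neglect label, scored by mean test AUC over 100 stratified
   80/20 splits with a label-permutation test.

Severity itself is the Centre of Cancellation (CoC): the mean normalised
horizontal position of cancelled targets, −1 … +1, averaged over the
letter and bells cancellation tests.

Because clinical cohorts of this kind are not shareable, the package
ships a synthetic-cohort generator (`simulate_cohort()`) with full ground
truth — anatomy, tract atlas, labelled streamlines, normative 4D series
with a planted seed-to-cortex network, subcortical lesions, and behaviour
whose rank correlation with total tract load is calibrated to a target
tau — so every stage is testable end to end. See the methods vignette
(`vignettes/methods.Rmd`) for the models, assumptions and design
decisions.

## Worked example

Simulate a cohort at the reference dimensions (43 patients, 27 basal
ganglia / 16 thalamus, target tau 0.3) and run the tract-load experiment:

```r
library(neglectdisc)

cfg <- synth_config(n_subjects = 10, n_timepoints = 60, seed = 20251001)
cohort <- simulate_cohort(cfg, with_connectome = TRUE)

kt <- kendall_tau(cohort$loads$total, cohort$behaviour$mean_coc)
res <- run_experiment3(cohort,
         run_config(classifier = classifier_config(n_splits = 100,
                                                   n_perm = 500),
                    seed = 20251001))
```

On this seed the cohort realises `kt$tau = 0.223` (p = 0.055) between
total tract lesion load and mean CoC, a presence chi-square of
χ²(1, N = 43) = 0.06 and a classifier mean AUC of 0.494 — a weak draw:
the generator plants the effect *in expectation* (target tau 0.3), and a
single 43-patient cohort scatters widely around it, which is exactly the
small-sample predicament such clinical analyses face. Averaging over
replicate cohorts shows the planted structure:

```r
an <- make_anatomy(synth_config(seed = 1))
set.seed(99)
stats <- sapply(1:20, function(r) {
  cfg <- synth_config(seed = 60000 + r)
  les <- make_lesions(cfg, an)
  loads <- lesion_load_table(les$lesions, an$atlas)
  beh <- make_behaviour(cfg, loads)$behaviour
  c(tau = kendall_tau(loads$total, beh$mean_coc)$tau,
    auc = repeated_cv_auc(loads[, 1:4], beh$neglect,
                          classifier_config(n_splits = 20))$mean_auc)
})
round(rowMeans(stats), 3)
#>   tau   auc
#> 0.301 0.607
```

Across 20 replicates the mean realised tau is **0.301** (target 0.3) and
the mean cross-validated AUC **0.607** (range 0.47–0.74) — multivariate
tract load predicts neglect above chance on average even though single
cohorts, like single tracts, are noisy.

The numbered scripts under `analysis/` run the full narrative at desk
scale — `01_simulate_cohort.R` writes a self-contained cohort directory
(NIfTI, TRK, CSV), `02`–`04` run the three experiments and write their
JSON/CSV summaries under `results/`.

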