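---
title: "Mapping spatial neglect after subcortical stroke: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spatial neglect after subcortical stroke: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neglectdisc` implements a three-part analysis of spatial neglect after
subcortical (basal ganglia or thalamic) stroke, built around indirect
estimates of brain disconnection from a patient's binary lesion mask:

1. **Lesion-network mapping** against a normative resting-state
   connectome, with voxel-wise frequentist and Bayesian inference on the
   association between network connectivity and neglect severity.
2. **Streamline-level structural disconnection** against a normative
   streamline set, with one-tailed permutation inference per streamline.
3. **Tract-wise lesion load** against a probabilistic tract atlas, with
   rank-correlation statistics and a random-forest classifier of the
   binary neglect diagnosis.

Real clinical cohorts of this kind are rarely shareable, so the package
also contains a synthetic-cohort generator with known ground truth; every
statistical claim made by the test suite is computed on such cohorts.

## Behavioural severity: the Centre of Cancellation

Neglect severity is quantified from cancellation tests (60-target letter
and 35-target bells sheets). For one sheet, each target's horizontal
position (cm from the patient's sagittal midline) is normalised by the
largest absolute target position, and the Centre of Cancellation (CoC) is
the mean normalised position of the *cancelled* targets: 0 for
symmetrical performance, +1 when only the extreme right-hand target was
cancelled. The severity measure is the mean CoC over available tests; a
patient with only one recorded test keeps that score as the sole measure.

Design choices worth noting:

* The normalisation denominator is the maximum absolute target position
  of the sheet (not the sheet half-width), which guarantees the nominal
  range $[-1, 1]$ is attained at the extreme targets.
* The binary neglect label is "CoC strictly above the cutoff in at least
  one available test". Cutoff values are configuration, not constants:
  empirically established cutoffs belong to the specific test forms, so
  the package requires them explicitly (the synthetic cohort uses 0.08
  for both tests, a value in the range used for these tests in clinical
  practice).
* A sheet with zero cancelled targets has no defined CoC; it propagates
  as an explicit missing value rather than being coerced to ±1, and the
  per-patient severity is then based on the remaining test(s).

## Lesion-network mapping

For every normative subject, the mean BOLD time course over the lesion
voxels (the *seed*) is correlated with every voxel's time course; the
Pearson correlations are Fisher z-transformed ($z = \mathrm{atanh}(r)$,
with $|r|$ clipped at $1 - 10^{-7}$) and averaged voxel-wise across
subjects. Voxels valid in fewer than half the subjects become missing,
and missing values are never imputed. Because activity inside and near
the seed correlates with itself by construction, maps are masked to
cerebral cortical grey matter (parcellation labels in the cortical set)
before statistics; the subcortical seed region and white matter are
excluded. Time series are consumed as supplied — the package assumes
upstream preprocessing — with an optional per-voxel linear detrend flag.

### Frequentist mapping

Per voxel, the t statistic of the severity slope in a single-regressor
GLM (equivalently $t = r\sqrt{(n-2)/(1-r^2)}$). Family-wise error control
uses maximum-statistic permutation: the severity vector is shuffled, the
map recomputed, and the maximum of $|t|$ (two-tailed) recorded; the
critical value is the $\lceil (1-\alpha) P \rceil$-th order statistic of
the $P$ permutation maxima, and observed statistics strictly above it are
significant. Permutation p-values use $p = (1 + \#\{ \max_b \ge t \}) /
(1 + P)$, so they are never zero. For $n \le 8$ the full permutation
group can be enumerated instead of sampled. Numerically perfect fits
($1 - r^2$ at machine zero) are reported at a documented cap of $10^8$.

The GLM has a single regressor plus intercept — no covariates — and
voxels valid in fewer than all patients are excluded (complete-case
analysis), matching the masked-map design.

### Bayesian mapping

Per voxel, BF$_{10}$ for "slope ≠ 0" with a zero-centred Cauchy prior on
the standardised effect $\delta$ (default scale $\sqrt{2}/2$, the common
default for standardised-slope priors; configurable). The marginal
likelihood ratio is evaluated by numerical integration of the noncentral-t
density of the observed statistic over the prior:
$\mathrm{BF}_{10} = \int t_{\nu}(t \mid \delta\sqrt{n})\,
\mathrm{Cauchy}(\delta; 0, s)\, d\delta \,/\, t_{\nu}(t \mid 0)$.
The substitution $\delta = s\tan\theta$ turns the Cauchy weight into a
flat measure on $(-\pi/2, \pi/2)$, where a fixed 129-node composite
Simpson rule is accurate to ~$10^{-8}$ relative error (verified against
adaptive quadrature in the tests) and vectorises over voxels. Observed
$|t|$ is clipped at 40 before integration: beyond that the central-t
density underflows while the BF is astronomically large, and no bin
boundary is anywhere near. BFs are binned by the usual conventions —
BF > 30 very strong, > 10 strong, > 3 moderate evidence for H1;
1 ≤ BF ≤ 3 anecdotal for H1; 1/3 ≤ BF < 1 anecdotal for H0; BF < 1/3 at
least moderate for H0 — with a BF of exactly 1 (measure-zero tie)
assigned to the anecdotal-H1 bin. This Bayesian model is the package's
own documented choice; no numerical agreement with any particular
external toolbox is claimed.

## Streamline disconnection

A streamline counts as disconnected by a lesion when any point of its
arc-length resampling (default step 0.5 mm, half a 1 mm voxel, so no
voxel can be skipped between samples at typical curvature; original
vertices always kept) falls in a lesion voxel after nearest-voxel
rounding. This covers streamlines terminating in and passing through the
lesion alike. Indicators are binary by design; no weighting by streamline
count is performed.

Streamlines disconnected in fewer than 5 patients (configurable) are
removed *before* the permutation null is formed, matching the stated
analysis order. Per surviving streamline the statistic is the pooled-
variance two-sample t (disconnected minus spared); inference is
one-tailed — damage is expected to increase severity — with max-t
permutation FWE across streamlines. Columns constant across patients
after filtering cannot be tested and are excluded with a message.
Significant streamlines are aggregated by the tract labels carried with
the streamline file; the atlas-side "recognise and cluster" assignment of
an external tractography tool is not re-implemented, so labels are an
input, and unlabelled streamlines are counted in an `unlabelled` bucket.

## Tract-wise lesion load

Binary load: the probabilistic tract map is thresholded at $p \ge 0.3$
(inclusive — a voxel at exactly 0.3 is kept) and the load is the damaged
fraction of the tract, $|L \cap T| / |T|$. The denominator is the tract
size, not the lesion size, keeping loads comparable across lesion sizes.
Weighted load: each lesioned voxel contributes its tract probability,
normalised by the tract's total probability mass so both measures share
the $[0,1]$ scale (and coincide on binary maps).

Associations with severity use Kendall's tau-b (tie-corrected — load
vectors tie at zero routinely) with the tie-adjusted normal approximation
for the two-sided p-value, Bonferroni-corrected over the per-tract tests.
The presence analysis (any nonzero load vs none, neglect vs no neglect)
uses Pearson's chi-square without continuity correction; with the counts of the
reference presence table (N = 43, 28 patients with load, 14 neglect
patients of whom 12 with load) only the uncorrected statistic reproduces
the reference value of 3.88, which is why no continuity correction is
applied.

## Random-forest classification

Forests with 100 trees, maximum depth 3 and a minimum node size to split
of 5 (ranger's `max.depth` / `min.node.size`, mirroring the usual
scikit-learn controls) predict the binary neglect label from the four
tract loads. Performance is the mean test-set ROC AUC over 100 stratified
80/20 splits — per-split AUCs are averaged rather than pooling
predictions, matching a looped cross-validation reading — and the AUC is
computed by the Mann–Whitney rank formula (cross-checked against pROC in
the tests). Significance comes from shuffling the labels 2500 times and
rerunning the identical procedure; each permutation generates fresh
stratified splits from its shuffled labels (stratification is only
meaningful with respect to the labels actually used) and fresh forests.
The p-value is $(1 + \#\{\mathrm{AUC}_b \ge \mathrm{AUC}\}) / (1 + B)$,
bounded below by $1/(1+B)$. The whole procedure is a deterministic
function of the configured seed. Calibration suites scale `n_splits` and
`n_perm` down through the configuration (the tests use 4 splits and
99–199 permutations per run); tree hyperparameters stay at their
defaults.

## The synthetic cohort

The generator emits everything the pipeline consumes on a 32³ voxel, 1 mm
template (all geometry scales with the grid; permutation suites then run
in minutes rather than hours):

* **Anatomy.** A spherical brain, two subcortical blobs (pseudo basal
  ganglia and pseudo thalamus), a 12-parcel cortical shell, and five
  fibre bundles with Gaussian cross-sections (σ = 1.4 mm) around curved
  centrelines: four association tracts (SLF, IOF, SOF, UF) that pass the
  subcortical blobs at varying distances and form the tract atlas, plus a
  corticospinal-like distractor bundle that pierces the thalamus blob but
  carries no weight in the severity model — echoing the clinical
  confound that corticospinal damage accompanies hemiparesis rather than
  neglect. Streamlines are jittered copies of each centreline constrained
  to lie inside the bundle's p ≥ 0.3 core.
* **Connectome.** Per normative subject, white-noise voxel series plus
  region latents: the subcortical blobs and exactly one cortical parcel
  share a latent (the planted network), every other parcel has a private
  latent, and light separable smoothing adds local spatial
  autocorrelation. Defaults are 100 subjects and 100 timepoints; the test
  suite uses 3–6 subjects and 30–40 timepoints, which suffices for the
  planted parcel to be the top-ranked cortical parcel.
* **Lesions.** 43 patients by default, split 27:16 between basal ganglia
  and thalamus as in the reference cohort; each lesion is an anisotropic
  ellipsoid centred in its blob with jittered position and a volume drawn
  from 10–80 voxels (clinically typical subcortical lesion volumes scaled to the template),
  clipped to the brain. Variable size and position produce variable
  encroachment on the adjacent tracts, so tract loads range from zero to
  a few percent — giving both the graded loads the rank statistics need
  and the load-present/load-absent split the presence analysis needs.
* **Behaviour.** Severity is a linear function of the [0,1]-scaled total
  tract load plus Gaussian noise. The signal amplitude is calibrated so
  that the *expected* Kendall tau-b between total load and severity
  equals the configured `effect_size` (default 0.3): the expectation has
  a closed form over patient pairs — each untied pair contributes
  $2\Phi(a\,|\Delta s|/(\sigma\sqrt{2})) - 1$ — and the amplitude is the
  root of that expression, found once per cohort. Severity is then
  anchored at the reference cohort's moments (mean 0.16, SD 0.27) and clipped
  to $[-1, 1]$. Each patient also receives realised letter and bells
  cancellation sheets whose hit patterns (cancel the k outermost targets
  on the severity's side, k chosen to minimise the CoC error) reproduce
  the intended severity to within the sheet granularity (< 0.02), so the
  CoC scoring path is exercised end to end. The anchored Gaussian-like
  severity matches the reference moments but is more symmetric
  than the clinical distribution (which concentrates near zero), so the
  synthetic neglect prevalence (~60%) exceeds the clinical one (~33%);
  none of the calibration claims depend on that prevalence.
* **Calibration cohorts.** Matrix-level generators bypass the image
  domain for the statistical calibration suites: spatially autocorrelated
  null map stacks, null binary disconnection matrices, and
  planted-disconnection cohorts in which a driver subset of patients
  receives a 2-SD severity shift and planted columns are near-copies of
  the driver indicator (5% per-entry flips keep the columns distinct
  without destroying the planted effect).

All generators are pure functions of (configuration, seed); reruns are
bit-identical, and the emitted files (NIfTI volumes, TRK streamlines,
CSV behaviour, YAML manifest, ground-truth JSON) reload losslessly.

### What passing tests do and do not show

The synthetic data are deliberately simple: spherical-shell cortex,
Gaussian tract profiles, ellipsoidal lesions, linear severity link,
homoscedastic noise, no scanner artefacts, no haemodynamics, no
registration error. Passing calibration and recovery tests therefore
demonstrates that the *statistical machinery* is correct — family-wise
error is controlled, planted effects of stated size are recovered at the
stated power, estimators agree with brute-force oracles — not that the
pipeline would reach the same clinical conclusions on real data, where
lesion shapes, tract geometry and behavioural distributions are far less
tame.

## Numerical and procedural choices

* Volumes entering one analysis must share shape and affine to within
  1e-4; mismatches are hard errors and nothing is resampled
  (normalisation is out of scope).
* Voxel indices are 1-based in the R API; the NIfTI affine applies to
  0-based indices internally. World-to-voxel mapping rounds half-up to
  the nearest voxel centre, making intersection tests deterministic.
* Streamline files are normalised to world mm on load (TRK voxel-mm
  coordinates are converted through the header affine with the half-voxel
  origin shift), removing on-disk dialect from downstream code.
* FWE thresholds use the order-statistic definition above; with the
  observed data excluded from the null, exchangeability gives an any-
  detection rate of $\lceil (1-\alpha)P \rceil$-based exactly near α,
  which the calibration suite checks empirically.
* Per-group analyses (basal ganglia / thalamus) reuse the identical code
  path with a patient filter; groups below the minimum size are skipped
  with a recorded reason.
* A single top-level seed determines every stage; reports are
  deterministic JSON with config echo, seed, per-stage counts and MD5
  hashes of any input files, and two runs with the same inputs are
  byte-identical.

## Problem sizes used by the packaged analyses

The numbered scripts under `analysis/` and the acceptance script run at
desk scale, chosen so a full pass completes in minutes on one CPU:
synthetic cohorts of 43 patients on the 32³ grid; connectomes of 5–10
subjects × 60–100 timepoints where lesion-network maps are needed;
100–500 permutations for mapping stages (the clinical-scale default of
10 000 remains the package default for real use); 500 replicate cohorts
for calibration and recovery estimates; classifier calibration with 4
splits × 99 permutations per replicate. These sizes are stated here as
the package's own reproducibility conditions.

## Known limitations

* The Bayesian voxel model is a standardised-slope Cauchy-prior BF; other
  toolboxes use different priors and will return different magnitudes.
* Tract assignment of streamlines relies on supplied labels.
* The synthetic severity distribution matches first and second moments of
  the reference cohort, not its skew (see above).
* No covariates (e.g. lesion volume) are implemented in the mapping GLMs,
  and no cluster-extent or TFCE inference is offered.
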