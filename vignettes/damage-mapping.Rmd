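---
title: "Normative z-score damage mapping of white matter: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative z-score damage mapping of white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmdamage)
```

## The problem

Multiple sclerosis damages white matter diffusely and focally, and several
quantitative MRI metrics are sensitive to that damage in different ways:
fractional anisotropy (FA, unitless) and radial diffusivity (RD, here in
10^-3^ mm^2^/s) from the diffusion tensor, the magnetisation transfer ratio
(MTR, percent) and the myelin water fraction (MWF, unitless fraction).
`wmdamage` implements a pipeline that makes these heterogeneous metrics
comparable by expressing each voxel of a patient's map as a z-score against a
healthy-control reference at the same location, then asks three questions:
how much damage does each tissue state carry, how strongly do the metrics
agree (between patients, and voxel-wise within patients), and which metric —
or which linear combination — best separates lesional from normal-appearing
tissue.

Because no imaging data ship with the package, a synthetic cohort generator
reproduces the statistical structure the analyses consume, with known ground
truth, so every stage is testable end to end.

## The pipeline

1. **Normative model.** For each metric, per-voxel sample mean `mu` and
   sample SD `sigma` (n - 1 denominator) over the control cohort. A patient's
   damage map is `z = (x - mu) / sigma`; a z of -1 means one control SD below
   the control mean at that voxel. Voxels with SD at or below `sd_floor` are
   flagged invalid and never emit z-scores. The small-sample bias of the
   sample SD at n = 27 (about 1%) is documented, not corrected.
2. **Tissue states.** A lesion probability map over patients, thresholded
   inclusively at 5%, restricts all analyses to lesion-susceptible white
   matter. NAWM is white matter at probability >= 0.80, inside that
   restriction, and strictly more than 5 mm (Euclidean, physical mm) from any
   lesion voxel. Lesion voxels split into T1L (T1-weighted intensity at or
   below Q1 - 1.5 IQR of the patient's NAWM intensity distribution) and T2L
   (the rest). Patients enter the cohort analyses only when all three states
   exceed 0.4 cm^3 (strict inequality).
3. **Summaries.** The global damage score is the median z per state; cohort
   contrasts are a one-sample t-test (NAWM vs 0) and paired t-tests (T2L vs
   NAWM, T1L vs T2L). Between-patient Pearson correlations use a
   Bonferroni-corrected threshold (default divisor 36, giving 0.05/36 =
   0.0014). Within-patient voxel-wise correlations are averaged across
   patients through the Fisher transform, with the SD reported on the raw r
   scale. Variance explained is the per-patient OLS R^2 (with intercept) of
   one metric on the other three, times 100.
4. **Composite score.** All included patients' white-matter voxels are pooled
   and a correlation-based PCA extracts the first component; the
   Kaiser-Meyer-Olkin index (anti-image partial correlations from the matrix
   inverse) reports sampling adequacy. The component is sign-oriented so the
   MWF weight is positive.
5. **ROC sensitivity.** Per patient and score, AUCs for T2L vs NAWM, T1L vs
   NAWM and T1L vs T2L, after orienting every score so that larger means more
   damaged. AUC is computed through midranks, which is exactly the
   Mann-Whitney U divided by n1\*n2 with ties counted 1/2; the empirical curve
   integrates (trapezoid) to the same number by construction.
6. **Reliability.** Dice overlap between two raters' masks, ICC(3,1)
   (two-way mixed, single measure, consistency) on extracted volumes, and a
   paired t-test for systematic conservativeness.

## The synthetic cohort generator

```{r}
spec <- cohort_spec(seed = 1)   # 27 controls, 105 patients, 40^3 grid, 1 mm voxels
cohort <- generate_cohort(spec)
result <- run_pipeline(pipeline_config(cohort_spec = spec))
```

The generator emulates, per subject:

* smooth per-metric baseline fields (Gaussian-smoothed white noise, sigma
  6 mm, amplitudes chosen so spatial structure is visible but subordinate to
  the mean: FA 0.45 +/- 0.06, RD 0.60 +/- 0.08, MTR 38 +/- 2.5%, MWF
  0.15 +/- 0.03), giving spatially non-trivial normative maps without real
  anatomy;
* voxel noise correlated across metrics with the group-mean within-patient
  correlation matrix as default (FA-RD -0.74, FA-MTR 0.38, FA-MWF 0.43,
  RD-MTR -0.52, RD-MWF -0.58, MTR-MWF 0.67), sampled by Cholesky
  factorisation;
* focal lesions as unions of 4-6 random spheres of 5-7 mm radius inside the
  white-matter core, with the innermost 35% of each sphere's voxels carrying
  T1-hypointense (T1L) ground truth. Lesion morphology is deliberately
  unrealistic: only the statistics downstream matter;
* per-tissue damage offsets drawn per patient, metric and state from the
  default effect table (means such as FA -0.31 in NAWM through MWF -7.31 in
  T1L, in control-SD units) with the corresponding between-patient SDs;
* a T1-weighted channel whose NAWM intensities are N(100, 10) and whose T1L
  (T2L) voxels are drawn truncated at least one NAWM-SD below (above) the
  generating Q1 - 1.5 IQR cutoff, so ground-truth labels are recoverable and
  the classification margin is explicit;
* two simulated raters who drop each lesion voxel with probability
  `p^depth` (depth = 6-connected erosion depth), concentrating disagreement
  at lesion boundaries, with rater 2 given the larger p so one rater is
  systematically more conservative.

**Calibration choice: damage is injected on the realised control reference.**
Patient voxel values in white matter are constructed as
`mean_hat + (delta + eps) * sd_hat`, where `mean_hat`/`sd_hat` are the
sample mean/SD fields of the *generated* control cohort — exactly the
reference the normative stage estimates. The alternative (injecting on the
population fields) makes every downstream z-estimate carry the inverse-chi
factor E[sigma/sigma_hat] (= 1.030 at n = 27), inflating configured effects
by about 3% and coupling patients through shared normative error. With the
realised-reference construction the configured z-unit effects are exactly
the estimands of the pipeline, the control self-z-scoring identity is exact,
and the null type-I error of the tissue-state tests is nominal. The
generator documents its RNG substream order (baseline fields, control ages,
control maps, then per patient: age, lesions, offsets, noise, T1w, raters),
so identical specs reproduce cohorts bit-identically.

The voxel-level SD of damage inside a tissue state is not identified by
group summary statistics; it is exposed as `within_state_sd` with a default
of 1 control-SD unit, a value typical of the dispersion seen in lesional z
maps. One consequence worth knowing: the within-patient correlations of a
*default* cohort exceed the configured noise correlations in magnitude,
because the state-dependent damage offsets add shared spatial structure
across metrics — exactly as in real cohorts. Correlation-fidelity checks
therefore use a homogeneous-effect cohort (zero effect table), where the
voxel correlation isolates the configured coupling.

What the generator does *not* emulate: scanner physics, partial volume,
registration error, anatomy-shaped lesion morphology, or spatially varying
noise SD. Passing tests therefore demonstrate the correctness of the
statistical machinery under the stated generative model, not robustness to
acquisition artefacts.

## Numerical and procedural choices

* **Quantile convention.** Q1/Q3 use linear interpolation between order
  statistics (`stats::quantile` type 7). The cutoff report records Q1 and
  IQR so alternative conventions are auditable.
* **Perilesional exclusion.** Voxel-centre distance <= 5 mm (computed in
  physical mm from the voxel geometry; anisotropic voxels handled by axis
  scaling) excludes a voxel from NAWM. The implementation is a physical-unit
  binary dilation, cross-checked in the tests against a brute-force
  all-pairs distance oracle on anisotropic grids.
* **Inclusion rule.** Strict (> 0.4 cm^3): a patient with exactly 400 voxels
  of 1 mm^3 in a state is excluded. The strictness is configurable.
* **Susceptibility threshold.** Inclusive (>= 5%), so a voxel lesioned in
  exactly 5% of patients is retained.
* **T1 cutoff reference.** The susceptibility-restricted NAWM (the mask the
  pipeline actually produces) supplies the reference intensity distribution.
* **Rater choice.** When two rater masks are available, segmentation uses
  the more conservative (smaller) one; the default synthetic pipeline
  segments on ground-truth masks and keeps the simulated raters for the
  reliability stage, so the recovery analyses are not confounded by rater
  noise.
* **Ties and degeneracies.** AUC ties count 1/2; paired t-tests with zero
  variance return t = 0, p = 1 when the mean difference is zero and are
  flagged as exact-constant otherwise; ICC(3,1) is undefined (NA, with a
  message) only when both between-subject and residual variance vanish;
  Dice of two empty masks is 1; KMO of a diagonal matrix is undefined (NA).
* **Bonferroni divisors.** 36 for the between-patient correlations and 10
  for the ROC comparisons, both configurable; 36 reproduces the corrected
  threshold of 0.0014.
* **PCA scaling.** Correlation-based (standardised) PCA over the pooled
  sample: near-equal weights across metrics with very different z-variances
  are only attainable on standardised inputs. Pooling is complete-case; no
  imputation. Eigenvalue > 1 retention is reported, component 1 is always
  used downstream.
* **Regression intercept.** The variance-explained regressions include an
  intercept, since z maps have strongly non-zero means inside lesions.

## Problem sizes

The default study conditions are 27 controls and 105 patients on a 40^3 grid
of 1 mm voxels, which keeps each tissue state above roughly 500 voxels per
patient and the full pipeline under a minute on one CPU. The test-suite
cohorts are scaled-down versions of the same generative model (26^3 grids
with 2-3 smaller lesions and a lowered inclusion volume, or 16^3 lesion-free
single-metric cohorts for the 200-replicate null calibration); correlation
fidelity uses 10^5 direct draws, and the homogeneous correlation-recovery
cohort uses 30 patients with >= 2000 white-matter voxels each.

## Known limitations

* Registration, bias-field correction, DTI/mcDESPOT fitting and lesion
  detection are out of scope; all volumes must arrive co-registered on a
  common grid, and lesion masks are inputs.
* The mass-univariate design ignores spatial autocorrelation; no
  mixed-effects or spatially aware correlation models are provided.
* Between-patient sampling noise bounds how closely a single synthetic
  cohort of 105 patients can reproduce configured per-state means: the
  cohort mean of a state with between-patient SD 1.97 has a standard error
  of 0.19 z even with a perfect pipeline.
* The ICC and Dice values of the simulated raters depend on the chosen
  boundary-perturbation model and are not calibrated to any particular
  human inter-operator study.
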