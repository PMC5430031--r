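---
title: "Methods: the SSM WMH~GMV pattern analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SSM WMH~GMV pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmpattern)
```

## The model and its assumptions

The Scaled Subprofile Model treats a cohort of gray matter volume maps as
a subjects × voxels matrix and asks for *covariance patterns*: spatial
profiles whose expression varies across subjects. The preprocessing
chain it assumes — tissue segmentation, spatial normalization to a common
template, modulation and smoothing — is consumed as given; the package
starts from masked NIfTI volumes.

Three steps define the decomposition:

1. **Log transform.** Voxelwise `ln x`. Multiplicative subject effects
   (global atrophy, residual scaling) become additive. The default
   `"strict"` policy refuses non-positive voxels; `"epsilon"` adds a
   small offset (default `1e-6` of the median masked value) because
   modulated VBM maps can hit exact zeros at tissue edges.
2. **Double centering.** Subtracting each subject's mean across voxels
   and each voxel's mean across subjects (adding back the grand mean)
   removes global subject level and mean anatomy; what remains is the
   subject-by-voxel interaction the covariance patterns live in.
3. **PCA.** A thin SVD retains `K = min(n − 1, p)` components: unit-norm
   voxel loadings and subject score factors `SSF = U·S`, so the centered
   data equal `SSF %*% loadings` exactly at full rank.

The WMH-related pattern is the linear combination of components whose
subject scores, together with total intracranial volume (TIV), best
predict log WMH burden under the Akaike Information Criterion. The
search is *exhaustive* over all subsets of the leading `k_max`
components up to `max_subset` members: winning subsets in this kind of
analysis are routinely non-contiguous (e.g. components 1, 2 and 6), so a
prefix-only search would be structurally unable to reproduce them. This
was a genuinely open reading — "the first subset with the lowest AIC"
could describe prefix sets — and the free-subset interpretation was
chosen precisely because it subsumes the other.

The composite pattern is `w = Σ β_k · loading_k` over the selected
components, with the OLS coefficients as weights; subject scores are the
projections of the centered profiles onto `w`, standardized by default
(group comparisons of scores are scale-free, and the log base cancels —
natural log is used throughout since any base change is absorbed by the
standardization). Under the `SSF = U·S` convention the raw scores equal
the fitted response minus the intercept and TIV contribution exactly,
which is what makes the compose→project algebra testable to machine
precision.

TIV enters the regression as a covariate, never by pre-residualizing the
response: head size is controlled *within* the model, so component
selection sees the same response every candidate model sees.

## Bootstrap reliability Z-maps

Pattern estimation is resampled at the subject level: each replicate
redraws subjects with replacement and reruns the entire chain — centering,
PCA, subset selection (by default re-selected per replicate; a
`fixed_subset` mode exists for variance attribution), composition. Two
numerical guards make the accumulated voxelwise mean/SD meaningful:

* **Sign alignment.** PCA and regression signs flip freely across
  resamples; every replicate pattern is flipped, if needed, to have
  non-negative inner product with the point-estimate pattern.
* **Degenerate SD.** Voxels whose replicate SD is below `1e-12` get
  `Z = sign(mean) · z_cap`; all Z values are capped at `z_cap = 50`,
  which preserves ranking while avoiding infinities in noiseless or
  near-noiseless constructions.

`Z = mean/SD` (the bootstrap mean in the numerator; a `"point"` option
uses the point-estimate pattern instead, since either reading is
defensible) is thresholded at `|Z| ≥ 2` into positive and negative
reliable-voxel masks. Resamples with fewer than 3 unique subjects, or on
which the replicate regression degenerates, are redrawn and logged.

Randomness uses one master seed that draws a per-iteration seed vector up
front; replicates are therefore reproducible independent of execution
order, and identical seeds give bit-identical Z-maps.

## Clinical derivations and inference

* Blood pressure groups follow the 140/90 rules on the mean of two
  measurements: *normotensive* = no hypertension history, unmedicated,
  below 140/90; *controlled* = history, medicated, below 140 systolic
  **and** 90 diastolic; *uncontrolled* = history and at or above 140
  **or** 90. A reading exactly at 140 or 90 counts as not controlled
  (clinical convention; the strict inequalities leave equality
  unassigned). Everything else — e.g. hypertensive-range pressure with no
  history — is recorded as *unclassified* rather than forced into a
  group.
* `logWMH = ln(100 · WMH/TIV)`; gray matter fraction `GMF = GMV/TBV`.
  A zero WMH volume is an error under the strict default; a configurable
  floor (`wmh_floor_cc`) substitutes a detection-limit volume when
  wanted.
* The group ANCOVA is an OLS with the unordered group factor plus
  covariates; the group F comes from the nested-model comparison, with
  uncorrected pairwise contrasts alongside (the customary follow-up to a
  significant omnibus F). The "ordinal" trend test is OLS of the
  standardized scores on the numeric group code 0/1/2 — the reported B
  and adjusted R² are OLS quantities, which is why a proportional-odds
  model is deliberately *not* used. Cognitive domain models control for
  age and education, and the four of them share a Bonferroni family
  (`min(1, 4p)`). All tests are two-tailed at α = 0.05.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, not MRI physics. In log space each subject's map is a smooth
mean anatomy plus `K = 3` orthonormalized Gaussian-blob patterns weighted
by subject loadings plus voxel noise — exactly the linear model the
pipeline's log transform recovers, so recovery algebra is exact at zero
noise. Defaults are the study conditions the package is tested under:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 64 | cohort size, groups 21/22/21 |
| grid / mask | 20³, 25 % | ≈ 2,000 masked voxels at 8 mm |
| `pattern_sigma_vox` | 2 | focal blobs, centres ≥ 3.5 σ apart |
| `loading_sds` | 2, 1.5, 1.2 | leading pattern ~6 % of total variance |
| `noise_sd` | 0.18 | between-subject residual of smoothed log VBM |
| `target_r` | 0.61 | population adjusted R² ≈ 0.345 for the fitted model |
| `group_shift` | 0.8 · SD | detectable ordered-group effect on loading 1 |
| cognition effects | −0.28 / −0.32 / 0 / 0 | memory and executive associations |

Loading 1 carries the clinical structure (ordered blood-pressure shift,
age slope, education shift); log WMH is drawn so its population
correlation with loading 1 is `target_r`, and WMH volume, blood
pressures, medication counts and history are derived consistently, so
the classifier reproduces the assignment exactly. Pattern *support* is
defined at half maximum of the generating blob (the standard FWHM
definition of a focal pattern's extent). An optional
`smoothing_fwhm_mm` convolves the noise field to emulate the spatial
autocorrelation of real VBM residuals; the default leaves noise
independent across voxels, matching the plain additive-Gaussian
generative premise.

What the generator does **not** emulate: lesion geometry, bias fields,
registration error, partial-volume effects, non-Gaussian site noise, and
anatomically realistic covariance topography. Passing recovery tests
therefore demonstrate the correctness and stability of the *estimator*
under its own model, not performance on real cohort data.

## Numerical choices

* **Sign convention.** Each loading's largest-magnitude element is made
  positive; PCA signs are otherwise arbitrary and would break
  reproducibility and bootstrap alignment.
* **Perfect fits.** A subset whose relative RSS falls below `1e-12` gets
  AIC `−∞`, so noiseless constructions resolve deterministically instead
  of overflowing the log.
* **Ties.** Equal AIC goes to the smaller subset, then the
  lexicographically earliest — determinism over optimism.
* **Effective rank.** The subset search stops at components whose
  eigenvalue exceeds `1e-12` of the leading one; numerically null
  components would only produce singular designs.
* **Conditioning.** Designs with condition number above `1e10` are
  errors naming the offending subset, not silent pseudo-inverses.
* **Centering checks.** `ssm_pca()` requires row/column means below
  `1e-8` of the data scale; reconstruction, orthonormality and variance
  conservation are tested at `1e-8`.
* **Geometry.** Affines must agree within `1e-4` absolute — loose enough
  for header rounding, tight enough to catch misregistered inputs.
  Masked vectors use the array-storage raster order (x fastest), fixing
  column identity across platforms and file orderings.

## Problem sizes in the test suite

The suite exercises the full default cohort (64 × 2,000) for recovery
and bootstrap checks — 50 seeds for selection/recovery properties, 200 to
500 bootstrap iterations, 500 replicates for null calibration — and small
cohorts (≈ 40 × 150) where the property under test is algebraic rather
than statistical. These sizes make the whole suite run in a few minutes
while keeping every statistical claim at the cohort scale the defaults
describe.

## Known limitations

* **Composite-weight inflation.** Because the composite weights are OLS
  coefficients on variance-scaled scores applied to *unit-norm*
  loadings, a weakly correlated low-variance component admitted by the
  exhaustive AIC search receives a voxel-space weight comparable to the
  informative component's (`β_k ∝ r_k / s_k`). At `n = 64` the AIC
  admission threshold is a partial correlation of roughly 0.18, so most
  seeds admit one or two such components, and the voxelwise correlation
  between the composite and the planted pattern has a practical ceiling
  near 0.9 (PCA estimation error) with a typical median near 0.7–0.75
  under the default cohort — the acceptance script reports the measured
  value. Subject *scores* are immune (score variance contributions scale
  with `r_k²`), which is why score-level recovery sits near 0.97. Users
  interpreting the voxel map should lean on the bootstrap Z-map, which
  suppresses exactly these unstable contributions, rather than the raw
  composite.
* Best-subset AIC is selection-biased: the fitted adjusted R² of the
  winning model overstates the population value slightly; the bootstrap
  re-selects per replicate precisely so this bias is part of the
  resampled variability.
* No voxelwise multiple-comparison machinery beyond the bootstrap
  threshold (no cluster-extent correction, no permutation nulls).
* Geometry is opaque: the package preserves affines but knows nothing of
  template space or anatomical labels.
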