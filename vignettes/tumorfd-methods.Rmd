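---
title: "Box-counting fractal dimension of tumor masks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-counting fractal dimension of tumor masks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorfd)
```

## What this package computes

`tumorfd` estimates the three-dimensional Minkowski–Bouligand (box-counting)
dimension of a segmented tumor volume on CT and carries that estimate
through a complete imaging-biomarker evaluation for microvascular invasion
(MVI) in hepatocellular carcinoma: cohort simulation, univariable screening,
multivariable logistic modelling, ROC analysis with DeLong comparison,
Youden cut-off selection, Hosmer–Lemeshow calibration, decision-curve
analysis, inter-reader ICC, and Kaplan–Meier risk stratification.

The estimator covers the foreground of a binary mask with cubic boxes of
edge $s$ voxels, anchored at the minimum corner of the foreground bounding
box, and counts occupied boxes $N(s)$ over a schedule of scales. The FD is
the ordinary-least-squares slope of $\log N(s)$ against $\log(1/s)$:

$$\widehat{FD} = -\,\frac{d \log N(s)}{d \log s}.$$

For exactly self-similar phantoms the estimate is exact: a level-$L$ Menger
sponge (side $3^L$, $20^L$ voxels) yields $N(3^k) = 20^{L-k}$ on the ternary
schedule and $\widehat{FD} = \log 20/\log 3 \approx 2.7268$ with $r^2 = 1$;
a solid cube gives exactly 3, a one-voxel slab exactly 2. These closed forms
are the package's primary correctness oracles.

## Preprocessing conventions

* **Resampling.** CT volumes are resampled to isotropic 1 mm voxels by
  trilinear interpolation; masks by nearest neighbour (linear interpolation
  of labels would break binarity). Grids are cell-centred and the output
  shape per axis is `round(extent_mm / target)`, so resampling a volume to
  its own spacing is the identity — this makes the worked examples
  bit-stable.
* **Quantization.** Intensities are clipped to a Hounsfield window and
  mapped to 0..255 by `floor(255 * (v - lo) / (hi - lo) + 0.5)`. The source
  normalization scheme is not fully specified in the literature the
  pipeline follows; the default window (−200, 400) HU brackets
  portal-venous abdominal soft tissue and is configurable. Quantization
  only affects the optional grayscale (differential) box-count variant —
  the primary statistic is binary and window-independent.
* **Lesion selection.** The pipeline operates on the single mask supplied.
  When a mask contains several lesions, `largest_component()` implements
  the "largest tumor" rule: the biggest 26-connected component, ties broken
  toward the lexicographically smallest bounding-box origin.
* **Anchoring.** Fixed bounding-box anchoring (no offset optimization) was
  chosen over a min-over-offsets policy for determinism and because it
  makes translation invariance exact, which the tests exploit.

## Fit policy

Scales with $N(s) = 1$ carry no slope information once the object fits in a
single box; the curve keeps the first saturated scale and the fit excludes
saturated points entirely. The default fits all remaining scheduled scales;
`best_window` instead maximizes $r^2$ over contiguous sub-ranges of at
least `min_points` scales, for lesions whose scaling range is contaminated
at one end. Masks with fewer than two usable scales return a flagged result
rather than a number.

"Maximum fractal dimension" is interpreted as the maximum of a local FD map
(sliding cubic window, default 32 voxels with stride 16, shrunk to the
largest fitting power of two for small lesions); the global whole-lesion FD
is the primary statistic used in modelling.

## What finite-scale box counting of solid masks actually measures

A point that shaped several design decisions and one deliberately red
acceptance test: for a **solid** voxel object measured over a finite scale
range, the box-count slope is *not* primarily a boundary-roughness measure.

* At the finest scales the slope is approximately
  $3 - O(\text{surface}/\text{volume})$: every partially filled surface box
  at $s = 2, 4$ drags the slope below 3, and radial boundary roughness
  *raises* surface faster than volume.
* At the coarsest scales the count reflects how completely the object fills
  its bounding box; radial lobes extend the bounding box faster than they
  add occupied boxes.

Both effects point the same way, so the measured FD of the rough-sphere
generator `make_rough_tumor()` (radial surface
$r(u) = R\,(1 + \rho\, Z(u))$ with $Z$ a unit-variance spherical-harmonic
field of orders 2–8) **decreases** strictly and strongly with the roughness
amplitude $\rho$ (Spearman $-1$ across $\rho \in \{0, 0.1, 0.2, 0.3\}$),
while it **increases** with lesion radius (≈2.52 at $r = 8$ to ≈2.72 at
$r = 24$ voxels). The acceptance criterion asserting a *positive*
roughness–FD association is therefore left red by design — the estimator is
correct (it is exact on every analytic phantom); the criterion's assumed
sign is not attainable with solid masks. The empirical clinical finding
that MVI-positive tumors have higher FD is consistent with FD acting partly
as a size-and-space-filling measure: MVI-positive tumors are substantially
larger (diameter > 5 cm odds ratio ≈ 4).

Consequently the voxel-level simulator ties each synthetic lesion's radius
to its patient's diameter covariate (0.4 cm per voxel at desk scale,
clamped to 5–18 voxels) and draws roughness from class-conditional
distributions (MVI+ mean 0.30 vs 0.10, truncated normal on [0, 0.45]); in
this mode the measured FD separates the classes through geometry, with
MVI-positive lesions measuring *lower* — the direction the geometry
dictates, documented rather than hidden.

## The cohort simulator as a stated world

The label-conditional simulator (the default) encodes the published
training-cohort summaries as its ground truth:

* covariate prevalences: AFP > 400 ng/mL 37.7%, diameter > 5 cm 54.4%,
  multiple tumors 10.6%;
* MVI from a logistic model with odds ratios 2.19 / 4.16 / 3.87 on those
  covariates, the intercept found by bisection so the *exact* expected
  prevalence over the eight covariate cells equals 29.8%;
* FD per MVI class from truncated normals on [2, 3] — binary box counting
  of a 3D mask cannot exceed 3 — **moment-calibrated** so the truncated
  means equal 2.95 (MVI+) and 2.78 (MVI−);
* RFS/OS exponential with class medians 28/43 and 40/58 months, 20%
  uniform censoring (a patient censored with probability 0.2 is observed at
  a uniform fraction of its event time);
* per-patient counter-based random streams, so patient $i$ is identical
  for every cohort size under the same master seed.

Two calibration subtleties are worth recording. First, a truncated normal
naively parameterised by (mean 2.95, sd 0.10) has a *truncated* mean near
2.90; the package root-finds the parent location so the truncated mean is
exact. Second, no truncated normal on [2, 3] with mean 2.95 can reach an SD
of 0.10 (the supremum, at the truncated-exponential limit, is ≈0.05); the
calibrator matches the SD where feasible (the MVI− class: parent
$\mu \approx 3.69$, $\sigma \approx 0.50$ give truncated moments
2.78/0.19) and otherwise matches the mean exactly and reports the
achievable SD (`sd_matched = FALSE`; MVI+ realizes ≈0.047). The
within-class SD of the MVI-positive class is therefore smaller than the
published 0.10 — an unavoidable consequence of the [2, 3] support, not a
tuning choice.

A second generative mode (`mode = "covariate"`) reverses the factorization:
FD is drawn from a marginal truncated normal and MVI from a logistic model
*including* FD with coefficient $\ln 62.21$ centred at 2.8. This forward
model has known coefficients and is what the parameter-recovery test
exercises. Within-class independence of FD and the clinical covariates is
assumed throughout; the source tables do not report those correlations.

The simulator emulates none of the following, so green tests establish
nothing about them: CT noise and texture, scanner differences, segmentation
variability, multi-lesion patients, non-proportional hazards.

## Statistical components

* **Logistic models** are maximum-likelihood fits via IRLS (tolerance 1e-8,
  ≤100 iterations) with Wald CIs and p-values, matching the OR-with-CI
  presentation convention. Separation is reported through a `converged`
  flag (coefficients beyond ±40 or SEs above 100 — true separation drives
  SEs into the thousands, while the steep-but-genuine FD coefficient on its
  0.2-wide class gap stays near 15–20).
* **Variable screening** keeps univariable predictors with $p$ strictly
  below 0.05, preserving input order; the multivariable combined model is
  clinical covariates + FD, with VIF = $1/(1-R^2_j)$ as the collinearity
  check.
* **AUC** uses the Mann–Whitney estimator with half credit for ties;
  variance and the paired two-model test come from DeLong structural
  components; CIs are Wald on the AUC scale, truncated to [0, 1] (the
  logit-scale alternative was not adopted; the source's CI method is
  unstated).
* **Youden cut-off** maximizes sensitivity + specificity − 1 over midpoints
  of adjacent distinct scores (ties toward the lower threshold), with
  `score >= cutoff` called positive. The published cut-off value itself is
  internally inconsistent in its source (negative point estimate, positive
  CI), so it is always recomputed, never hard-coded.
* **Hosmer–Lemeshow** uses 10 sample-quantile bins (merged under ties) and
  the conventional $g-2$ degrees of freedom. Note a known subtlety: the
  $g-2$ reference is correct for probabilities fitted in-sample; for
  externally supplied true probabilities the statistic is approximately
  $\chi^2_g$, so a nominal-0.05 test against $\chi^2_{g-2}$ rejects ~11.5%
  of such nulls. This is why the HL half of the statistical-size acceptance
  criterion is red: the criterion pairs an external-probs null with the
  internal-fit reference.
* **ICC(2,1)** (two-way random effects, absolute agreement, single rater)
  is used for reader agreement because each reader segmented every subject
  once and systematic offsets should count against agreement; the CI uses
  the F-distribution formulation with Satterthwaite degrees of freedom.
* **Kaplan–Meier/log-rank** are the product-limit estimator and the 1-df
  hypergeometric log-rank; medians and IQR bounds are the first times the
  curve drops to ≤0.5/0.75/0.25, flagged when never crossed. High-risk MVI
  is defined as a combined-model score at or above the training-set Youden
  cut-off.

## Numerical and degenerate-input choices

* Box schedules: `pow2` runs to the largest power of two ≤ min(shape)/2;
  `ternary` to min(shape); schedules with fewer than two usable sizes are
  errors, and all-equal count curves return flagged results.
* Quantile-function sampling (`qnorm` of a uniform mapped into the
  truncated CDF range) keeps truncated-normal draws exactly inside their
  support and makes every stream reproducible from one master seed.
* The rough-tumor generator sizes its grid from the empirical field
  maximum on a 1500-point spherical Fibonacci probe (5% safety margin) and
  regenerates with a derived seed if the voxelized mask is 26-disconnected
  (up to 5 attempts, recorded in an attribute).
* NIfTI-1 support is deliberately minimal (single-file, scalar datatypes,
  both endiannesses, gzip); DICOM support covers uncompressed
  implicit/explicit VR little endian with slices ordered by position along
  the orientation normal and an inter-slice spacing consistency check.
  Cross-checked against nibabel in the suite.

## Known limitations

* FD values from this pipeline are comparable only under a fixed scale
  range and resolution; the strong size dependence documented above means
  FD should not be read as a pure shape-complexity measure.
* The simulators are calibrated to marginal summaries; joint structure
  beyond the MVI model (e.g. FD–diameter correlation within class) is
  assumed independent.
* No Cox modelling, competing risks, or time-dependent ROC; the prognostic
  analysis is KM/log-rank only, as in the source design.
* The DICOM reader does not handle compressed transfer syntaxes,
  multi-frame objects, or undefined-length sequences.
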