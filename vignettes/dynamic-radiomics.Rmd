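---
title: "Dynamic radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynrad)
```

## The model

`dynrad` analyses 4-phase dynamic contrast-enhanced MRI (plain/"mask",
arterial, portal venous, equilibrium). For a tumour ROI in one phase it
computes a vector of 484 static radiomics features Ψ(x(t)); across the four
phases each static feature traces a trajectory Ψ(x(t₁)), …, Ψ(x(t₄)), and a
map Φ: ℝ⁴ → ℝ²⁰ turns every trajectory into 20 dynamic features. Logistic
signatures are then built on the static columns (SR), the dynamic columns
(DR), or the union of what the first two selected (DSR), and compared on a
held-out cohort.

The biological premise is that pathology that alters lesion blood supply
(e.g. microvascular invasion in hepatocellular carcinoma) changes the
*shape* of the contrast wash-in/washout trajectory more than any single
phase's appearance; dynamic features are designed to read that shape, and
their ratio forms also cancel inter-scanner and inter-patient intensity
scale.

## Preprocessing conventions

* **Resampling** to 1 × 1 × 1 mm voxels: trilinear for volumes,
  nearest-neighbour for masks (masks stay binary). The output grid covers
  the same physical extent as the input.
* **Normalisation** x' = (x − μ)/σ. The statistics default to the whole
  volume, with a `region = "mask-only"` switch; image-level statistics are
  the default because the transform is presented as an image normalisation,
  and quantization makes the choice irrelevant for texture features.
* **Order**: the pipeline resamples first and normalises second by default
  (`normalize_first` flips this); with whole-volume statistics the two
  orders differ only through interpolation smoothing.
* **Quantization**: equal-width bins between the ROI minimum and maximum,
  labelled 1…64 (ROI min → 1, max → 64). A fixed bin *count* — rather than
  fixed bin width — is used so the levels are invariant to affine intensity
  rescaling; a constant ROI maps entirely to level 1 by convention.

## The static feature bank

7 intensity features (mean, population variance, skewness, kurtosis,
energy, 64-bin histogram entropy, range — skewness/kurtosis of a
zero-variance ROI are 0 by convention) plus a fixed 53-feature texture
roster: 22 GLCM, 13 GLRLM, 13 GLSZM and 5 NGTDM features
(`texture_feature_roster()`; shipped as `inst/extdata/feature_roster.json`).
The roster was fixed so that the counts sum to 53 while covering all four
texture families and every feature the signature analyses rely on by name
(Maximum probability, Cluster prominence, Correlation1, Correlation2,
Autocorrelation, Long run emphasis, Long run low gray-level emphasis,
Gray-level variance, Small zone emphasis, Contrast). Where the same
statistic exists in two families, the name goes to the family the analyses
attribute it to (Contrast is the NGTDM feature; the GLCM analogue is named
Inertia, its classical synonym). `Correlation1` is the Haralick form
(Σ ij·p − μxμy)/(σxσy) and `Correlation2` the normalised-covariance form
Σ (i−μx)(j−μy)p/(σxσy); for a symmetric co-occurrence matrix the two
coincide numerically, and both are kept for roster fidelity.

GLCM and GLRLM matrices are built per direction over the 13 unique 3D
directions at distance 1 and the feature values averaged; GLSZM zones use
26-connectivity; NGTDM neighbourhoods are the in-ROI part of the
26-neighbourhood. Voxels outside the mask never enter any matrix. Degenerate
ROIs (single voxel, constant level) produce degenerate matrices and
documented conventions, never exceptions.

**Wavelet features.** A single-level separable 3D wavelet transform yields
8 sub-bands (LLL … HHH; the first letter is the x-axis filter), each of
which is quantized inside the mask and run through the 53-feature texture
bank (8 × 53 = 424). The default transform is *stationary* (undecimated)
with periodic boundary handling so that each sub-band stays on the input
grid and the mask applies voxel-for-voxel; the decimated orthogonal variant
exists for verification (its sub-band energies sum to the input energy —
the Parseval identity — which the tests check to 1e-6 relative). The
default wavelet is coif1 (haar and db2 are available); filters are
hard-coded decomposition taps whose sum is √2.

## Dynamic feature conventions

With the time grid defaulting to phase indices t = (1, 2, 3, 4) (a config
option accepts representative acquisition-delay seconds instead; indices
are the default because the fits are against an unspecified t):

* **Integrated**: mean, population variance, CV = sd/mean (NaN when the
  mean is 0).
* **Discrete**: segments are the consecutive phase pairs
  (plain–arterial, arterial–portal, portal–equilibrium), with the earlier
  phase in the RCR denominator. The RACR denominator is the mean of all
  four phase values ("relative *average* change rate"); a config flag
  offers the segment-midpoint mean reading instead. Zero denominators give
  NaN, which the modeling stage median-imputes from training data.
* **Fitting**: all three models are linear in their parameters and solved
  by exact least squares (shared pseudoinverse across all series, so the
  construction of a 9680-column cohort matrix is one matrix product per
  model family). The quadratic curvature is
  QK(t) = |2a|/(1 + (2at + b)²)^{3/2} with its maximum at the vertex
  −b/(2a) (reported unconstrained); when a = 0 the curvature is identically
  0 and (T_maxQK, QK_max_feature) = (t₁, 0) by convention. The exponential
  curvature is implemented exactly as the construction defines it,
  EK(t) = |α eᵗ|/(1 + α e^{2t})^{3/2}; note this is not the analytic
  curvature of α eᵗ + β (which would carry α² e^{2t}) — a
  `corrected_curvature` flag provides the exact form, but the printed form
  is the default for fidelity to the construction. Because EK need not have
  an interior maximum and is undefined where 1 + α e^{2t} ≤ 0 (possible for
  α < 0), T_maxEK is found by a vectorised grid-refinement search on
  [t₁, t₄] (five rounds of 101-point grids, final step < 1e-6; invalid
  points excluded; an all-invalid profile yields NaN). The "curvature at
  the maximum feature value" is evaluated at the time point of the
  *observed* series maximum, earliest on ties.

Thresholds for degeneracy (|a| < 1e-12, |α| < 1e-12) catch floating-point
residue from constant series fitted by least squares.

## Modeling conventions

* **ICC**: two-way random effects, absolute agreement, single measurement —
  ICC(2,1) — computed from ANOVA mean squares; a feature passes when both
  intra- and inter-observer ICC exceed 0.8. Zero between-subject variance
  makes the ICC undefined and the feature fails.
* **Pipeline order** (training data only): median imputation of non-finite
  values → drop constant columns → z-score → F-test at α = 0.05 (one-way
  ANOVA per feature; equivalent to the pooled t-test for two classes) →
  LASSO (glmnet) with the penalty maximising mean AUC over 5 repeats of
  stratified 5-fold cross-validation → unpenalised logistic fit on the
  survivors → Youden-optimal probability threshold on the training ROC.
  The maximum-AUC rule (not 1-SE) is used; empty LASSO selections fall back
  to the smallest penalty with ≥ 1 nonzero coefficient; cohorts too small
  to cross-validate (fewer than 4 per class per fold) select the penalty by
  BIC along the path instead.
* **Evaluation**: AUC by the Mann–Whitney rank formulation with DeLong 95%
  CI; accuracy/sensitivity/specificity at the training-derived threshold;
  paired two-sided DeLong tests for AUC comparisons (the comparison test is
  a package choice; degenerate variance returns p = 1). The validation
  cohort is touched once, for final evaluation — no validation quantity
  feeds back into any transform, which the tests verify by permuting
  validation labels.

## What the synthetic data emulate — and what they do not

`generate_cohort()` builds ellipsoidal lesions (radii 5–9 mm by default)
on a quiet background in 48³ volumes at 1 mm isotropic, with class-specific
4-point enhancement trajectories (negative class: moderate arterial wash-in
with slow washout, (100, 160, 140, 120); positive class: stronger wash-in
and faster washout, (100, 180, 130, 105) — the perfusion pattern expected
when portal venous inflow is compromised), a zero-mean correlated random
field inside the lesion (amplitude 10 vs 18, correlation length 1.5 vs 2.5
voxels) for class-dependent texture heterogeneity, and additive Gaussian
noise (σ = 5; a Rician option exists). Reader variants for ICC studies
perturb masks by dilation/erosion plus fractional boundary flips.

`generate_feature_series()` skips images and emits per-phase feature
matrices directly. Its *temporal-only* design gives every patient × feature
cell four iid N(10, 1.5) draws, order-sorted; class 0 places them
monotonically across phases (rising or falling with probability 1/2), class
1 in a zigzag order (rank patterns (1,3,2,4) or (4,2,3,1), probability 1/2
each). Every phase thus receives the same distribution over order-statistic
ranks in both classes, so per-phase class marginals are matched *exactly*
by construction and a static model cannot beat chance; only the ordering
across phases — what dynamic features read — carries the label. This was
chosen over shifted "peaked vs rising" templates because it satisfies the
marginal-matching requirement provably rather than approximately.

These phantoms validate the machinery, not clinical performance: they have
no anatomy, no registration error, no MR physics (no bias field, k-space
sampling or coil profiles), uncorrelated inter-feature structure, and a
temporal signal far cleaner than patient data. Passing tests demonstrate
that the pipeline recovers the kinds of signal it claims to recover, with
no leakage and exact feature accounting — not that any particular clinical
AUC is attainable.

## Problem sizes used by the tests and the acceptance script

Simulation sizes were chosen as the smallest that make the statistical
assertions stable: texture oracles run on ≤ 4×4×2 toy ROIs against
exhaustive enumeration; the image smoke test uses 6 patients at 20³ voxels;
the null-safety check uses 200 training + 200 validation patients with 200
features; the temporal-recovery experiment uses 300 training and 150
validation patients, 60 features, over 10 replicate cohorts. The
acceptance script (`scripts/acceptance.R`) re-runs all of these from
scratch under a caller-supplied seed.

## Known limitations

* NIfTI input only (no NRRD/DICOM); no registration, bias-field or motion
  correction — per-phase masks are assumed to delineate the same lesion.
* The 53-feature roster is fixed; shape/morphology and Laplacian-of-Gaussian
  features are out of scope.
* One examination per patient: the dynamic construction summarises phases
  within a single study, not longitudinal series.
* The exponential curvature is reported in its defining (uncorrected) form
  by default; analyses comparing curvature magnitudes across packages
  should set `corrected_curvature = TRUE`.
* Clinical covariates, nomograms, calibration and decision-curve analyses
  are not implemented.
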