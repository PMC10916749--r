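---
title: "Whole-brain FDG-PET radiomics versus a 3D CNN: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain FDG-PET radiomics versus a 3D CNN: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`petrad` implements, end to end, a whole-brain FDG-PET study design that
discriminates healthy controls (HC) from dementia patients two ways — with a
neural network on selected radiomic features, and with a 3D convolutional
network on the raw volumes — and then asks which model is more *confident*,
by comparing the per-subject probability scores of the two arms with a
paired t-test. This vignette explains the model and procedure choices, the
tunable parameters, what the synthetic cohort does and does not emulate, and
the numerical conventions.

## The study design in one paragraph

All volumes live in a common template space (79 × 95 × 69 voxels of
2 × 2 × 2 mm). Every volume is scaled to its in-brain global mean and
smoothed with an isotropic 8 mm FWHM Gaussian. From the whole-brain volume
of interest, 215 radiomic features are extracted per subject (79 first-order
plus 136 texture features over six gray-level matrix families, after
discretization into 32 bins). Minimum-redundancy maximum-relevance (MRMR)
ranking keeps the top 10% (21 of 215), then Pearson pruning discards any
feature correlating at |r| ≥ 0.30 with an already-kept one. The surviving
features feed a small feed-forward network; in parallel a 3D CNN reads the
volumes directly. Both arms share one held-out test set of 20 subjects
(10 HC, 10 patients). Per-subject winning-class probabilities (0–100) of the
two arms are then compared per group with a paired two-tailed t-test.

## Synthetic cohort generator

No patient data are distributed; `generator_config()` +
`simulate_cohort()` produce a cohort with the statistical structure the
analysis assumes:

* **Demographics.** 125 controls (age ~ N(64.8, 11.33²)) and 85 patients
  (age ~ N(73.9, 6.8²), split 38 AD-like, 2 MCI-like, 25 DLB-like,
  20 FTD-like), ages truncated to [20, 95] by redrawing.
* **Geometry.** The template brain is a centred ellipsoid with semi-axes
  40% of each grid dimension — a deliberate geometric stand-in that avoids
  any atlas download. Subtype lesions are ellipsoids in grid-fraction
  coordinates: AD-like posterior temporo-parietal, DLB-like occipital,
  FTD-like frontal, each roughly 4–6% of the brain volume. The MCI-like
  pattern reuses the AD-like region, because the cases it emulates are
  MCI-to-AD converters. These labels are conventions on a phantom, not
  anatomy.
* **Signal model.** Each subject is a constant baseline (1.0) plus a
  low-frequency Gaussian-filtered field (24 mm FWHM, SD 0.03 — the
  between-subject heterogeneity), with the lesion applied as a
  *multiplicative* reduction (`hypometabolism_factor`, default 0.75)
  *before* the final smoothing, so lesion borders show PET-like
  partial-volume blur; multiplicative voxel noise (SD 0.05) is added, the
  volume is smoothed at 8 mm FWHM and scaled to unit in-brain mean.
  The heterogeneity SD of 0.03 was chosen once so that the cohort is
  strongly separable — the regional 25% reduction clearly dominates
  between-subject variability, mirroring a carefully adjudicated clinical
  cohort in which both classifiers are expected to be essentially perfect —
  while keeping single features overlapping enough that classification is
  not trivial on one coordinate.
* **Reproducibility.** Every subject draws from an own stream seeded by a
  deterministic hash of `(seed, subject_id)`, so cohorts are byte-identical
  across runs and independent of generation order.

What the generator does **not** emulate: scanner physics, attenuation and
scatter, anatomical atlas regions, age-dependent metabolism, or multi-center
batch effects. Passing tests on this phantom therefore validate the
*pipeline machinery and its statistics*, not clinical performance on real
FDG-PET.

## Preprocessing

`global_mean_scale()` divides by the in-mask mean (out-of-mask voxels are
carried along but never enter features). The scale target is 1.0: any
positive target is equivalent downstream because discretization works on the
in-mask [min, max] range. `smooth_volume()` is a separable discrete Gaussian
(σ = FWHM / (2√(2 ln 2)) per axis, truncated at 4σ, unit mass) with
**mirror-reflect** boundary handling, so constant volumes are exact fixed
points and interior mass is conserved to well under 0.1%.

## Voxel-wise t-maps

`voxelwise_glm_t()` contrasts one subject against a control group with an
age covariate: per voxel, OLS of intensity on [intercept, patient indicator,
age], t = indicator coefficient / SE, df = n − 3. The two-sided p is
reported with a direction flag (`hypo` keeps t < 0) because the sidedness of
the original procedure is not stated; `hypo` at p < 0.01 is the default
reading. Cluster extraction labels suprathreshold voxels with
**18-connectivity** (the SPM convention; 6 and 26 are options) and keeps
clusters *strictly larger* than 100 voxels. Voxels with (near-)zero residual
variance are flagged and set to t = 0 rather than propagating division
noise. Thresholding is uncorrected by design; random-field corrections are
out of scope.

## Radiomic features

Discretization is fixed-bin-number over the in-mask range:
`level = min(floor((x − min)·N/(max − min)) + 1, N)` with N = 32; the
maximum clamps into the top bin; a constant region maps to bin 1. This makes
every downstream feature invariant to positive rescaling of the input.

The 215-entry manifest is fixed and versioned by `feature_manifest()`:

* **79 first-order**: 17 morphology (voxel-count volume, face-count surface
  area, compactness family, PCA axis lengths, bounding box, centre-of-mass
  shift), 24 intensity statistics (moments, percentiles by the
  linear-interpolation rule, MAD family, energy/RMS), 26 intensity-histogram
  statistics on the 32-bin histogram (including entropy, uniformity and
  histogram-gradient features), 11 intensity-volume-histogram features, and
  the local intensity peak (mean in a 1 cm³ sphere at the hottest voxel).
  Morphology features are constant across subjects sharing the template
  mask — intentional: the whole-brain VOI design makes them uninformative
  for selection, and MRMR ranks them last.
* **136 texture** over six families. GLCM and GLRLM are directional: counts
  are accumulated over the 13 unique 3D direction vectors and contribute
  *both* a merged-matrix feature set (pooled counts, rotation-robust) and a
  direction-averaged set (features per direction, then averaged), 25 + 25
  and 16 + 16; GLSZM (26-connected equal-level zones by size), GLDZM (same
  zones by city-block distance to the mask border, border = 1), NGLDM
  (dependence counts with tolerance α = 0 in the 26-neighbourhood, stored
  as k + 1 so the 1/j² emphasis weights are always defined) and NGTDM
  (per-level sums of |level − neighbourhood mean|) are inherently 3D and
  contribute 16, 16, 17 and 5. Including both aggregations of the two
  directional families is exactly what closes the budget at 136 and mirrors
  how IBSI-style frameworks report them.

Degenerate inputs yield `NaN`-flagged features (e.g. NGTDM busyness with a
single gray level), never silent drops; the selection stage is the one
place that removes non-finite features, with a report.

## Feature selection

MRMR is the greedy mutual-information **quotient** variant: relevance is
MI(feature; label), redundancy the mean MI with already-ranked features, and
the criterion relevance / max(redundancy, ε); the first pick is by pure
relevance. MI is estimated on 16 equal-frequency bins. Coarser binning (4
bins is a common default) turned out to misrank features here: with few
equal-frequency bins the bin containing the class boundary mixes both
groups, so a *perfectly* separating continuous feature caps well below the
label entropy, while a coarsely discrete feature whose own steps happen to
align with the class split scores higher despite overlapping groups. At
cohort sizes around 200 (a dozen subjects per bin), 16 bins estimate MI
finely enough that fully separating features rank first. Ties break by manifest order, so ranking is
deterministic. `select_top_fraction()` keeps ⌊0.10 × 215⌋ = 21 features;
`pearson_prune()` walks them in rank order and keeps a feature only when its
|r| with *every* kept feature is strictly below 0.30, preserving the most
relevant member of each correlated clique. The kept set's correlation matrix
is attached as a certificate and re-checked on every run. Selection
statistics are computed on non-test subjects only (training + validation, the
"90%"), so no test information leaks into the feature choice.

## The two classifiers

Both arms consume one `make_split()`: the test set is 10 subjects per group
drawn first (the shared 20-subject test design), then ~10% of the cohort
becomes validation, the rest trains.

* **Radiomics arm** (`train_feature_nn()`): z-score normalization fitted on
  training subjects only (sample SD; zero-SD features are a named error),
  then a feed-forward net input → 16 → 8 → 2 with ReLU and softmax — small
  on purpose, since only a handful of features survive pruning. Full-batch
  Adam (lr 0.01, 300 epochs), keeping the best-validation-loss weights.
* **CNN arm** (`train_cnn_3d()`): three blocks of 3³ "same" convolution →
  batch normalization → ReLU → 2³ max-pool with 8/16/32 channels, then
  FC(64) → 2 with softmax. Minibatch Adam (lr 10⁻³, batch 10), batch
  statistics during training and running statistics at inference,
  best-validation weights kept. Convolution runs as one BLAS product per
  sample via im2col. Input shape is configurable; the desk-scale default is
  32³ centre crop/pads.

Scores are the winning-class posterior × 100; the two class scores always
sum to 100, and the predicted class is the one scoring ≥ 50. Everything is
seeded: same config + seed gives identical score tables.

## Score comparison

`compare_models()` joins the two arms' test scores by subject, splits by
true group, and reports mean/SD per model plus the **paired** two-tailed
t-test on per-subject differences (t = mean(d)/(SD(d)/√n), df = n − 1). The
paired form is the deliberate reading of the design: the same ten subjects
per group are scored by both models, and on the published worked-example
table (shipped as `reference_scores()`) only the paired form reproduces the
printed p = 0.0004 for the HC group — a verification the test suite
performs. Identical score columns are reported as "no difference" rather
than an error.

## Problem sizes and the desk-scale configuration

`desk_study_config()` is the configuration used by the package's own
replication runs and the acceptance script: the full cohort design (125 +
85) on a half-resolution grid of 40 × 48 × 35 voxels of 4 mm with the CNN
at 32³ and 12 epochs. Half resolution preserves the cohort's statistical
structure (the lesion covers the same brain fraction; smoothing and noise
are in mm and scale with it) while a full two-arm run completes in a few
minutes on one CPU. Full-resolution extraction of a single volume takes on
the order of seconds and is exercised separately in the test suite.

## Numerical conventions and edge cases

* Percentiles everywhere use R's type-7 linear interpolation.
* Skewness/kurtosis are population moments; kurtosis is excess.
* Voxel coordinates in reports are 1-based array indices.
* NGTDM coarseness is capped at 10⁶ for uniform regions; busyness/contrast
  are NaN when fewer than two gray levels are present.
* The age draw truncates to [20, 95] by rejection.
* Derived seeds stay below 2³¹; per-subject streams come from a 31-adic
  string hash of the subject id folded with the master seed.

## Known limitations

The brain mask and lesions are ellipsoids, so morphology features carry no
between-subject information; the generator's heterogeneity is a single
smooth field rather than structured anatomical variability; the CNN is a
small fixed architecture without augmentation or hyperparameter search; the
t-map step supports quality control of the synthetic lesions, not clinical
inference. Subtype-versus-subtype classification is explicitly out of
scope.
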