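---
title: "Radiomics classification with confidence-gated reader fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics classification with confidence-gated reader fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radfuse)
library(dplyr)
```

radfuse implements a complete radiomics pipeline for binary tumor
classification from masked grayscale volumes — the setting of a prostate
ultrasound study in which 10-second transrectal video clips, treated as
stacked 3D volumes, are segmented and mined for texture descriptors that
discriminate malignant from benign glands. This vignette explains the
models, the conventions behind every numeric choice, and what the
synthetic-data generators do and do not emulate.

## The descriptor catalog and the numeric panel

The catalog (`catalog_features()`) enumerates 851 descriptors: on the
original image, 14 shape, 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16
GLSZM and 5 NGTDM descriptors (107), plus the 93 non-shape descriptors
replicated over the 8 sub-bands of a single-level stationary wavelet
transform (744). Shape descriptors depend only on mask geometry and are
therefore defined only for the original image.

Numeric extraction (`extract_selected()`) covers the 14-feature panel that
a LASSO selection typically lands on in this setting — spanning first-order
(Range, Skewness, Median), GLCM (ClusterProminence, ClusterShade,
Correlation), GLSZM (ZoneEntropy, GrayLevelNonUniformity,
LargeAreaHighGrayLevelEmphasis, SizeZoneNonUniformityNormalized,
SmallAreaHighGrayLevelEmphasis) and GLDM
(LargeDependenceLowGrayLevelEmphasis) — on the original image and five
wavelet sub-bands. Every other catalog descriptor deliberately raises a
"not implemented" error from `feature_value()` rather than silently
returning a number: catalog closure is an invariant, not an aspiration.

### Conventions (all configurable via `extraction_config()`)

* **Discretization**: fixed bin width (default 25 intensity units, matching
  an 8-bit grayscale range) anchored at the masked minimum:
  `level(v) = floor((v - min)/w) + 1`. Applied independently per image
  type, so each wavelet sub-band is binned on its own masked range. This
  is the dominant convention in standard radiomics tooling; bin width is a
  free parameter because acquisition dynamic ranges differ.
* **Wavelet transform**: single-level, undecimated (stationary), separable,
  with periodic boundary extension — undecimated so the sub-bands keep the
  input extents and the segmentation mask applies unchanged. Default
  family is Coiflet-1; Haar is available and is what the test suite uses
  on tiny phantoms (its 2-tap filter fits grids the 6-tap Coiflet cannot).
  Sub-band key letter *i* names the filter applied along axis *i*.
* **GLCM**: symmetric co-occurrence matrix per direction over the 13 unique
  3D offsets at distance 1, features averaged over directions that contain
  at least one masked pair. A direction with zero marginal variance has
  Correlation defined as 1 (degenerate perfect dependence).
* **GLSZM**: zones are 26-connected components of equal level
  (6-connectivity available). Labelling is delegated to
  igraph's connected components over an equal-level adjacency list; a
  brute-force flood fill is the independent test oracle.
* **GLDM**: dependence counts include the center voxel (d >= 1) and use
  level-difference cutoff alpha = 0 by default.
* **Degenerate ROIs**: a single-level ROI yields the documented closed-form
  values (ClusterShade/Prominence 0, Correlation 1, Skewness 0, one zone)
  instead of erroring, so batch extraction never aborts.

## Feature selection

The chain is fixed: ICC reproducibility filter, univariate screen,
zero-variance filter, repeated-CV LASSO; each stage's survivors are a
subset of its input.

* **ICC**: two-way random-effects, absolute-agreement, single-rater
  ICC(2,1), the standard choice when the two segmenters are regarded as a
  random sample of raters and absolute reproducibility (not mere
  consistency) matters. The retention threshold of 0.8 is boundary
  *inclusive*. Features with zero total variance have undefined ICC and
  fail the filter.
* **Screen**: Welch's t-test (no per-feature variance-homogeneity check is
  plausible at radiomics scale) and the Mann–Whitney U test; a feature
  survives if significant on *either* test by default. The lenient OR
  reading is chosen because the LASSO prunes downstream; a strict AND flag
  exists.
* **LASSO**: logistic loss on the 0/1 labels (a linear-loss flag exists),
  features standardized to zero mean/unit variance first, path over 100
  log-spaced penalties from the data-derived `lambda_max` (the smallest
  penalty with an all-zero solution) down to `lambda_max * 1e-4`. The
  penalty is chosen by the minimum of the mean cross-validated deviance
  over `n_repeats` independent stratified 10-fold partitions — the
  CV-minimum rule, not the 1-SE rule, since the goal is a single precise
  penalty. The default of 50 repeats is a deliberate scale-down of the
  brute-force many-repeat schemes sometimes reported: on synthetic cohorts
  the chosen penalty stabilizes (SD below half a grid step) well before 20
  repeats, so further repetition only burns CPU.

One honest caveat pinned by a test: the size of the LASSO active set is
*not* strictly monotone along the path — a feature can drop out
transiently as the penalty relaxes. The tests check the trend rather than
a strict inequality, because the strict version is simply not a theorem.

## Classifiers

Both models consume the selected-feature table and emit per-case
malignancy probabilities.

* **RBF-SVM** (`train_svm()`): standardize (scaler fitted on training rows
  only) then an RBF-kernel SVM; `C` in `10^-2..10^3` and `gamma` in
  `10^-4..10^1`, one order of magnitude at a time, chosen by mean
  stratified 10-fold CV accuracy (an AUC criterion and a half-decade
  refinement pass are options). Probabilities come from a sigmoid fitted
  to *out-of-fold* decision values at the chosen pair — calibration never
  sees a case's own training fit.
* **Random forest** (`train_rf()`): tree count from
  `{10, 100, 1000, 10000}` by the same CV criterion, evaluated cheaply by
  growing one maximal forest per fold and scoring its leading subsets of
  trees. A case's probability is the fraction of trees voting malignant.

A hash-guard test asserts the no-leakage contract: perturbing held-out
rows cannot change the chosen hyperparameters.

## The fusion rule

Given the SVM probability $P_{SVM}$, RF probability $P_{RF}$ and a
radiologist's binary verdict $V_R$, define confidences
$S_{SVM} = |0.5 - P_{SVM}|$ and $S_{RF} = |0.5 - P_{RF}|$ and the fused
score

$$S = \frac{S_{SVM}}{0.5} P_{SVM} + \frac{0.5 - S_{SVM}}{0.5}\left(
\frac{S_{RF}}{0.5} P_{RF} + \frac{0.5 - S_{RF}}{0.5} V_R\right).$$

This is a nested convex combination with weights $2S_{SVM}$ and $2S_{RF}$:
a confident SVM dominates, an uncertain SVM defers to the RF, and two
maximally uncertain models hand the case to the reader. Consequences the
tests pin down: $S \in [0,1]$ always; $S = P_{SVM}$ when $P_{SVM} \in
\{0,1\}$; $S = V_R$ when both probabilities are 0.5; $S$ is non-decreasing
in $V_R$; and $S$ is *deliberately not monotone* in $P_{RF}$ — the RF
contribution $2|0.5-P_{RF}|P_{RF}$ peaks inside $(0, 0.5)$. That
non-monotonicity is a property of confidence gating, not a bug, and a test
exists so nobody "fixes" it.

Binary calls threshold the fused score at 0.5 with ties going to
malignant; the threshold is explicit because a fused score of exactly 0.5
occurs at natural boundary inputs. Inputs are validated, never clamped:
the caller owns probability calibration. Each reader tier contributes one
verdict column; reducing a multi-reader panel to one verdict is out of
scope.

## Evaluation

AUC uses the Mann–Whitney identity with ties counted half, which an
exhaustive pair-counting oracle confirms for every n <= 30.
Sensitivity/specificity/precision carry exact Clopper–Pearson 95%
intervals by default (Wilson optional) — exact because the relevant
cohorts are small (validation arms of ~15–19 cases per class), where
asymptotic intervals under-cover. Paired AUCs are compared with the DeLong
placement method (implemented in-package, cross-checked against pROC, and
calibrated in a 10^4-replicate null simulation); a label-permutation
alternative exists for comparing against a binary verdict arm, whose
two-point ROC makes the normal approximation doubtful. Cohen's kappa comes
from the 2x2 table; expected agreement of exactly 1 returns kappa 0 with a
warning.

`cohort_summary()` gates the per-variable test on Shapiro–Wilk normality
within groups — t-test when normal, Mann–Whitney otherwise — and uses the
chi-square test for categorical variables. The Brown–Forsythe
(median-centered Levene) statistic is computed for variance homogeneity
reporting; attributing *normality* testing to Levene's test, as sometimes
seen, is a category error this package deliberately corrects.

## Synthetic data: what it emulates, and what it does not

The generators provide every input the pipeline needs with known ground
truth:

* `gen_feature_table()`: Gaussian features in correlated blocks (size 10,
  within-block correlation `block_rho`) via a shared-factor model, with
  `k_informative` features mean-shifted by `effect_size` within-class SDs
  in the malignant class. Gaussian marginals match the t-test branch of
  the screen; a log-normal flag exercises the rank-based branch. The
  informative index set is returned so recovery is measurable.
* `gen_rater_pairs()`: shared subject effects plus independent per-rater
  noise, so the true ICC is exactly
  `sigma_subject^2 / (sigma_subject^2 + sigma_noise^2)`.
* `gen_reader_calls()`: case-independent Bernoulli verdicts at a stated
  sensitivity/specificity. The default tiers (junior 0.63/0.67, senior
  0.63/0.87) are typical of junior vs senior MRI readings in this setting.
* `gen_roi_volumes()`: benign volumes are smooth correlated Gaussian
  fields (correlation length 3 voxels) rescaled to an 8-bit-like grayscale
  range (mean 128, SD 30); malignant volumes add a high-frequency
  component (SD 40 gray levels, correlation length 0.5 voxels) emulating
  the textural heterogeneity of malignant tissue. Masks are centered
  ellipsoids. Setting the heterogeneity to 0 is the null case.

None of this simulates prostate anatomy, ultrasound speckle physics, or
video temporal dynamics, and the feature-table generator does not emulate
the heavy-tailed, strongly dependent marginals of real radiomics output.
Passing tests therefore demonstrate that the *machinery* is correct and
calibrated — not that any particular clinical performance level would be
attained on real patients.

## Problem sizes and cost choices

The defaults used by the test suite and the acceptance script are sized
for a laptop-class single core: selection recovery runs 200 x 100 tables
over 10–20 seeds with 3 CV repeats; the fusion-benefit simulation runs 20
replicates of a 300-patient cohort with 30 features (effect size 0.45,
chosen so the classifiers land at validation AUC ~0.75–0.80, the
moderate-accuracy regime where reader hand-off is informative) with
reduced tuning grids; texture oracles run on 100 random grids up to 5^3;
the DeLong null uses 5,000–10,000 replicates at n = 100. Larger grids,
more repeats and bigger cohorts are plain configuration changes.

## Known limitations

* Only the 14-feature panel is computed numerically; the remaining 837
  catalog descriptors are enumerable but raise on evaluation.
* No spacing-aware resampling or intensity normalization; the voxel
  spacing is carried but not used by the implemented features.
* NIfTI is the only volume format (no NRRD backend).
* SVM probability calibration fits a two-parameter sigmoid; with perfectly
  separable training data the logistic fit is weakly identified (the
  probabilities saturate, which is harmless for ranking but optimistic in
  magnitude).
* The fused score inherits whatever miscalibration the input probabilities
  carry; it is a decision rule, not a calibrated posterior.
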