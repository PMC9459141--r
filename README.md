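# radfuse

Radiomics texture features, reproducibility-aware LASSO feature selection,
RBF-SVM / random-forest probability models, and a confidence-gated fusion of
classifier probabilities with a radiologist's verdict — the full analysis
chain used to predict prostate cancer from transrectal ultrasound video
clips (treated as stacked 3D grayscale volumes with a segmentation mask),
built as a tested, reusable R package that runs end to end on synthetic
data with known ground truth.

## Who this is for

Imaging researchers who want the *machinery* of a radiomics
classification study — masked texture-feature extraction, the
ICC → univariate screen → variance filter → repeated-CV LASSO selection
chain, tuned probabilistic classifiers, reader fusion, and small-cohort
diagnostic statistics with exact intervals — as composable, pipe-friendly
functions with every stage testable against an oracle.

## The core model

**Features.** A catalog of 851 descriptors (107 on the original image: 14
shape, 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM; plus
93 non-shape descriptors on each of 8 stationary-wavelet sub-bands = 744).
A 14-feature texture panel spanning first-order, GLCM, GLSZM and GLDM
classes over the original image and five wavelet sub-bands is computed
numerically, each feature verified against an exhaustive brute-force
reference.

**Selection.** Features must be reproducible across segmenters
(two-way random-effects, absolute-agreement ICC ≥ 0.8), pass a Welch
t-test / Mann–Whitney screen, have nonzero variance, and survive an
L1-penalized logistic regression whose penalty λ minimizes the mean
cross-validated deviance over repeated stratified 10-fold partitions.

**Fusion.** With `S_SVM = |0.5 − P_SVM|` and `S_RF = |0.5 − P_RF|`, the
fused malignancy score is the nested convex combination

    S = 2·S_SVM·P_SVM + (1 − 2·S_SVM) · [ 2·S_RF·P_RF + (1 − 2·S_RF)·V_R ]

so a confident SVM decides, an uncertain SVM defers to the RF, and two
maximally uncertain classifiers hand the case to the reader verdict `V_R`.
Calls threshold `S` at 0.5, ties to malignant.

**Evaluation.** Mann–Whitney AUC with full ROC curves, exact
Clopper–Pearson 95% CIs for sensitivity/specificity/precision, Cohen's
kappa, and paired DeLong AUC comparisons.

## Worked example

A full synthetic study — 231 patients (113 benign / 118 malignant), 100
features of which 10 are informative at 1 SD effect — from generation to
the six evaluated arms:

```r
library(radfuse)

cfg <- pipeline_config(
  cohort = cohort_config(n_benign = 113, n_malignant = 118,
                         p_features = 100, k_informative = 10,
                         effect_size = 1, block_rho = 0.3),
  n_repeats = 5, C_grid = 10^(-1:2), gamma_grid = 10^(-3:0),
  n_estimators_grid = c(100, 500), cv_folds = 10, seed = 42L)
out <- run_pipeline(cfg, outdir = "demo_run")

out$selection
#> <selection_report>
#>   ICC filter: 99 / 100 features retained
#>   screen: 14 survivors; variance filter: 14; LASSO: 12 selected at lambda = 0.004376

glance(out$models$svm)
#> # A tibble: 1 × 5
#>   kind      C gamma cv_score n_features
#>   <chr> <dbl> <dbl>    <dbl>      <int>
#> 1 svm      10 0.001    0.935         12

dplyr::select(out$evaluation, split, arm, auc, sensitivity, specificity, kappa)
#> # A tibble: 12 × 6
#>    split      arm         auc sensitivity specificity kappa
#>    <chr>      <chr>     <dbl>       <dbl>       <dbl> <dbl>
#>  1 validation svm       0.971       0.889       0.882 0.771
#>  2 validation rf        0.971       0.833       0.941 0.772
#>  3 validation reader_jr 0.747       0.611       0.882 0.489
#>  4 validation reader_sr 0.742       0.778       0.706 0.484
#>  5 validation svm_rf_jr 0.993       0.889       1     0.886
#>  6 validation svm_rf_sr 0.967       0.833       1     0.829
#>  ...
```

Reading this: the screen cut 100 candidate features to 14 and the LASSO
kept 12 of them (10 informative features were planted); the tuned SVM
reaches cross-validated accuracy 0.935; on the held-out splits both
classifiers clearly beat the simulated readers (AUC ~0.97 vs ~0.74), and
fusing them with a reader verdict keeps or improves that performance. The
effect size here (1 SD) is generous so the example is sharp; the package's
fusion-benefit simulation (`simulate_fusion_benefit()`) uses a harder
0.45 SD regime where classifiers land near AUC 0.75–0.80 and fusion adds
~0.04–0.06 AUC on average.

Single pieces compose in the same way:

```r
fuse_cohort(p_svm = 0.7, p_rf = 0.3, v_r = 1)$s_mlad
#> [1] 0.712

roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc
#> [1] 0.75
```

Volumes work too: `gen_roi_volumes()` makes class-textured masked
volumes, `extract_selected()` computes the 14-feature panel on them, and
`write_roi_volume()`/`read_roi_volume()` round-trip NIfTI image/mask
pairs.

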