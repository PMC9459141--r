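Package: radfuse
Title: Radiomics Texture Features, LASSO Selection, and Classifier-Reader
    Fusion for Ultrasound Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiomics-based binary tumor classification from
    masked grayscale volumes: a catalog of 851 radiomics descriptors with
    numeric extraction of a 14-feature texture panel (first-order, GLCM,
    GLSZM, GLDM classes over the original image and stationary wavelet
    sub-bands); reproducibility filtering by intraclass correlation;
    univariate screening and repeated cross-validated LASSO feature
    selection; RBF support vector machine and random forest probability
    models; a confidence-gated fusion rule that cascades classifier
    probabilities into a radiologist verdict; and full diagnostic
    evaluation (ROC/AUC, exact binomial confidence intervals, Cohen's
    kappa, paired DeLong AUC comparison). Includes synthetic-data
    generators for feature tables, rater pairs, textured volumes and
    reader verdicts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
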