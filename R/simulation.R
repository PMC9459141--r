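# Simulation study of the fusion rule: does cascading two moderately
# accurate classifiers into a reader verdict improve on the best single
# classifier? Mirrors the design of a reader-comparison study: per seed, a
# synthetic cohort is generated, models are trained on the training split,
# and all arms are scored on the validation split.

#' Fusion-benefit simulation
#'
#' For each seed: generate a two-class cohort, split it, train the RBF-SVM
#' and random forest on the training split, predict malignancy
#' probabilities on the validation split, simulate a senior-reader verdict
#' at the profile's sensitivity/specificity, fuse with [fuse_cohort()],
#' and record the validation AUC of every arm. The default cohort is
#' calibrated so the classifiers land near AUC 0.75-0.80, the regime where
#' a confidence-gated reader hand-off is informative.
#'
#' @param n_seeds number of independent replicates.
#' @param cohort a [cohort_config()] template (its seed is overridden per
#'   replicate).
#' @param reader a [reader_profile()] for the simulated radiologist.
#' @param C_grid,gamma_grid,n_estimators_grid,n_folds classifier tuning
#'   settings (reduced defaults keep the replicate cost modest).
#' @param base_seed offset added to the replicate index.
#' @return A tibble with one row per seed and columns `seed`, `auc_svm`,
#'   `auc_rf`, `auc_reader`, `auc_mlad`.
#' @export
simulate_fusion_benefit <- function(n_seeds = 20,
                                    cohort = cohort_config(
                                      n_benign = 150, n_malignant = 150,
                                      p_features = 30, k_informative = 10,
                                      effect_size = 0.45, block_rho = 0.3),
                                    reader = reader_profile(0.63, 0.87),
                                    C_grid = 10^(-1:2),
                                    gamma_grid = 10^(-3:0),
                                    n_estimators_grid = c(100, 500),
                                    n_folds = 5, base_seed = 0L) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    seed <- base_seed + s
    cfg <- cohort
    cfg$seed <- seed
    tab <- gen_feature_table(cfg)
    sp <- split_cohort(tab, test_fraction = 0.25, val_fraction = 0.2,
                       seed = seed)
    feats <- feature_columns(tab)
    svm <- train_svm(sp$train, C_grid = C_grid, gamma_grid = gamma_grid,
                     n_folds = n_folds, seed = seed)
    rf <- train_rf(sp$train, n_estimators_grid = n_estimators_grid,
                   n_folds = n_folds, seed = seed)
    val <- sp$validation
    p_svm <- predict_proba(svm, val[feats])
    p_rf <- predict_proba(rf, val[feats])
    v_r <- gen_reader_calls(val$label, reader, seed = seed + 10000L)
    fused <- fuse_cohort(p_svm, p_rf, v_r)
    tibble(seed = seed,
           auc_svm = roc_auc(p_svm, val$label)$auc,
           auc_rf = roc_auc(p_rf, val$label)$auc,
           auc_reader = roc_auc(as.numeric(v_r), val$label)$auc,
           auc_mlad = roc_auc(fused$s_mlad, val$label)$auc)
  })
}
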