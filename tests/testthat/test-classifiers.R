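make_cohort <- function(n_per_class = 60, p = 6, k = 3, effect = 2, seed = 1) {
  gen_feature_table(cohort_config(n_benign = n_per_class,
                                  n_malignant = n_per_class,
                                  p_features = p, k_informative = k,
                                  effect_size = effect, seed = seed))
}

test_that("the cohort split is stratified, exhaustive and reproducible", {
  tab <- make_cohort(100, p = 4)
  a <- split_cohort(tab, 0.25, 0.2, seed = 3)
  b <- split_cohort(tab, 0.25, 0.2, seed = 3)
  expect_identical(a, b)
  rows <- sort(c(attr(a$train, ".row"), attr(a$validation, ".row"),
                 attr(a$test, ".row")))
  expect_equal(rows, seq_len(nrow(tab)))
  # stratification: class balance preserved in each split
  for (s in a) expect_equal(mean(s$label), 0.5, tolerance = 0.05)
  expect_error(split_cohort(tab, 0.99, 0.99, seed = 1), "sum < 1")
})

test_that("an 8:2 split of a 170-row pool gives 136/34", {
  tab <- make_cohort(85, p = 3)
  sp <- split_cohort(tab, test_fraction = 0, val_fraction = 0.2, seed = 1)
  expect_equal(nrow(sp$train), 136)
  expect_equal(nrow(sp$validation), 34)
  expect_equal(nrow(sp$test), 0)
})

test_that("SVM separates separable data and tunes by CV accuracy", {
  tab <- make_cohort(30, p = 2, k = 2, effect = 6, seed = 2)
  m <- train_svm(tab, C_grid = c(1, 10), gamma_grid = c(0.01, 0.1),
                 n_folds = 5, seed = 1)
  expect_s3_class(m, "radfuse_model")
  expect_equal(m$cv_score, 1.0)
  p <- predict_proba(m, tab[feature_columns(tab)])
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(p, tab$label)$auc, 0.99)
})

test_that("label-permuted data gives chance-level CV accuracy", {
  set.seed(6)
  tab <- make_cohort(100, p = 5, k = 0, effect = 0, seed = 6)
  m <- train_svm(tab, C_grid = 1, gamma_grid = 0.1, n_folds = 5, seed = 2)
  expect_lt(abs(m$cv_score - 0.5), 0.1)
})

test_that("duplicating training rows leaves the chosen SVM pair unchanged", {
  # fixed partition: each duplicate sits in the same fold as its original
  tab <- make_cohort(25, p = 2, k = 2, effect = 6, seed = 4)
  foldid <- rep_len(1:5, nrow(tab))
  m1 <- train_svm(tab, C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1),
                  n_folds = 5, foldid = foldid, seed = 9)
  dup <- dplyr::bind_rows(tab, tab)
  m2 <- train_svm(dup, C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1),
                  n_folds = 5, foldid = c(foldid, foldid), seed = 9)
  expect_equal(m1$hyperparameters, m2$hyperparameters)
})

test_that("RF tuning honors the grid and emits vote-fraction probabilities", {
  tab <- make_cohort(25, p = 2, k = 1, effect = 5, seed = 3)
  m <- train_rf(tab, n_estimators_grid = 10, n_folds = 5, seed = 1)
  expect_equal(m$hyperparameters$n_estimators, 10L)
  p <- predict_proba(m, tab[feature_columns(tab)])
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(p * 10 == round(p * 10)))  # fractions of 10 trees
  m2 <- train_rf(tab, n_estimators_grid = c(10, 100), n_folds = 5, seed = 1)
  expect_true(m2$hyperparameters$n_estimators %in% c(10L, 100L))
  # strongly separating feature: malignant cases score high
  expect_gt(min(p[tab$label == 1]), 0.7)
})

test_that("probability predictions are deterministic and schema-checked", {
  tab <- make_cohort(25, p = 3, k = 2, effect = 2, seed = 5)
  m <- train_svm(tab, C_grid = 1, gamma_grid = 0.1, n_folds = 5, seed = 1)
  newdata <- tab[rep(1, 2), feature_columns(tab)]
  p <- predict_proba(m, newdata)
  expect_equal(p[1], p[2])
  bad <- tab[feature_columns(tab)]
  names(bad)[1] <- "wrong_name"
  expect_error(predict_proba(m, bad), "schema mismatch")
})

test_that("SVM probabilities are monotone in the decision value", {
  tab <- make_cohort(40, p = 2, k = 2, effect = 1, seed = 7)
  m <- train_svm(tab, C_grid = 1, gamma_grid = 0.1, n_folds = 5, seed = 1)
  x <- as.matrix(tab[m$features])
  xs <- radfuse:::apply_scaler(x, m$scaler)
  dv <- attr(predict(m$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  p <- predict_proba(m, tab[m$features])
  ord <- order(dv)
  expect_true(all(diff(p[ord]) >= -1e-12) || all(diff(p[ord]) <= 1e-12))
})

test_that("perturbing held-out rows cannot change chosen hyperparameters", {
  tab <- make_cohort(50, p = 4, k = 2, effect = 1, seed = 8)
  sp <- split_cohort(tab, 0.25, 0.2, seed = 2)
  fit_on <- function(train) {
    m <- train_svm(train, C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1),
                   n_folds = 5, seed = 4)
    r <- train_rf(train, n_estimators_grid = c(10, 50), n_folds = 5, seed = 4)
    list(svm = m$hyperparameters, rf = r$hyperparameters)
  }
  h1 <- fit_on(sp$train)
  # scramble the test rows entirely; training is unaffected
  sp$test[feature_columns(tab)] <- sp$test[sample(nrow(sp$test)),
                                           feature_columns(tab)]
  h2 <- fit_on(sp$train)
  expect_identical(h1, h2)
})

test_that("both models reach validation AUC > 0.7 in the reference regime", {
  hits_svm <- hits_rf <- 0L
  for (s in 1:4) {
    tab <- gen_feature_table(cohort_config(n_benign = 150, n_malignant = 150,
                                           p_features = 30, k_informative = 10,
                                           effect_size = 1, block_rho = 0.3,
                                           seed = 300 + s))
    sp <- split_cohort(tab, 0.25, 0.2, seed = s)
    svm <- train_svm(sp$train, C_grid = 10^(0:2), gamma_grid = 10^(-2:0),
                     n_folds = 5, seed = s)
    rf <- train_rf(sp$train, n_estimators_grid = 100, n_folds = 5, seed = s)
    f <- feature_columns(tab)
    if (roc_auc(predict_proba(svm, sp$validation[f]),
                sp$validation$label)$auc > 0.7) hits_svm <- hits_svm + 1L
    if (roc_auc(predict_proba(rf, sp$validation[f]),
                sp$validation$label)$auc > 0.7) hits_rf <- hits_rf + 1L
  }
  expect_gte(hits_svm, 3L)
  expect_gte(hits_rf, 3L)
})
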