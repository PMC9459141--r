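# RBF-SVM and random-forest probability models over a selected-feature
# table, with grid search by stratified k-fold cross-validation. The
# standardization scaler is fitted on training rows only; validation/test
# rows never influence hyperparameters.

#' Stratified train/validation/test split
#'
#' Splits a labeled table into disjoint, exhaustive train, validation and
#' test row sets, stratified by label and reproducible under `seed`. The
#' test fraction is taken from the full cohort; the validation fraction is
#' taken from the remaining (non-test) pool, matching a "hold out the test
#' set, then split the rest 8:2" design.
#'
#' @param table feature table with a 0/1 `label` column.
#' @param test_fraction fraction of all rows held out for testing; 0 gives
#'   a two-way train/validation split of the pool.
#' @param val_fraction fraction of the non-test pool used for validation.
#' @param seed integer RNG seed.
#' @return List of tibbles `train`, `validation`, `test`, each carrying a
#'   `.row` attribute with the original row indices.
#' @export
#'
#' @examples
#' tab <- gen_feature_table(cohort_config(n_benign = 40, n_malignant = 40,
#'                                        p_features = 5, k_informative = 2))
#' sp <- split_cohort(tab, test_fraction = 0.25, val_fraction = 0.2, seed = 1)
#' vapply(sp, nrow, integer(1))
split_cohort <- function(table, test_fraction = 0.25, val_fraction = 0.2,
                         seed = 1L) {
  check_feature_table(table)
  if (test_fraction < 0 || test_fraction >= 1 ||
      val_fraction <= 0 || val_fraction >= 1 ||
      test_fraction + val_fraction >= 1) {
    abort("`test_fraction` and `val_fraction` must lie in [0, 1) x (0, 1) with sum < 1.")
  }
  set.seed(seed)
  y <- table$label
  test_ix <- val_ix <- integer(0)
  for (cls in sort(unique(y))) {
    ix <- which(y == cls)
    n_test <- round(length(ix) * test_fraction)
    t_ix <- sample(ix, n_test)
    rest <- setdiff(ix, t_ix)
    v_ix <- sample(rest, round(length(rest) * val_fraction))
    test_ix <- c(test_ix, t_ix)
    val_ix <- c(val_ix, v_ix)
  }
  train_ix <- setdiff(seq_len(nrow(table)), c(test_ix, val_ix))
  out <- list(train = table[sort(train_ix), ],
              validation = table[sort(val_ix), ],
              test = table[sort(test_ix), ])
  for (nm in names(out)) {
    if (nrow(out[[nm]]) > 0L && length(unique(out[[nm]]$label)) < 2L) {
      abort(sprintf("the %s split contains a single class; adjust fractions.", nm))
    }
  }
  attr(out$train, ".row") <- sort(train_ix)
  attr(out$validation, ".row") <- sort(val_ix)
  attr(out$test, ".row") <- sort(test_ix)
  out
}

fit_scaler <- function(x) {
  list(center = colMeans(x), scale = apply(x, 2, sd))
}

apply_scaler <- function(x, scaler) {
  sc <- ifelse(scaler$scale == 0, 1, scaler$scale)
  sweep(sweep(x, 2, scaler$center), 2, sc, "/")
}

cv_metric <- function(truth, prob, metric) {
  if (metric == "accuracy") mean((prob >= 0.5) == (truth == 1L))
  else roc_auc(prob, truth)$auc
}

model_matrix <- function(table, features) {
  missing <- setdiff(features, names(table))
  extra <- setdiff(feature_columns(table), features)
  if (length(missing)) {
    abort(sprintf("missing feature columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  as.matrix(table[features])
}

#' Train an RBF-kernel support vector machine with grid search
#'
#' Pipeline: per-feature standardization (fitted on the training rows) then
#' an RBF-kernel SVM. The cost `C` and kernel width `gamma` grids vary
#' logarithmically, one order of magnitude at a time, by default; the best
#' pair is chosen by mean stratified `n_folds`-fold cross-validated
#' accuracy (or AUC via `metric`). Class probabilities come from a sigmoid
#' (logistic regression) calibrated on out-of-fold decision values at the
#' chosen hyperparameters.
#'
#' @param train feature table with a 0/1 `label` column.
#' @param C_grid,gamma_grid hyperparameter grids (defaults `10^(-2:3)` and
#'   `10^(-4:1)`).
#' @param n_folds CV folds (default 10).
#' @param metric model-selection criterion: `"accuracy"` (default) or
#'   `"auc"`.
#' @param refine if `TRUE`, a second half-decade grid around the winning
#'   decade refines `C` and `gamma`.
#' @param foldid optional integer fold assignment (length `nrow(train)`,
#'   values in `1..n_folds`) for a fixed CV partition; generated from
#'   `seed` when `NULL`.
#' @param seed integer RNG seed for the fold partition.
#' @return An object of class `radfuse_model` (kind `"svm"`).
#' @export
train_svm <- function(train, C_grid = 10^(-2:3), gamma_grid = 10^(-4:1),
                      n_folds = 10, metric = c("accuracy", "auc"),
                      refine = FALSE, foldid = NULL, seed = 1L) {
  check_feature_table(train)
  metric <- match.arg(metric)
  if (!length(C_grid) || !length(gamma_grid)) abort("empty hyperparameter grid.")
  y <- train$label
  if (min(table(y)) < n_folds) abort("need >= `n_folds` rows in each class.")
  features <- feature_columns(train)
  x_raw <- as.matrix(train[features])
  scaler <- fit_scaler(x_raw)
  x <- apply_scaler(x_raw, scaler)
  set.seed(seed)
  if (is.null(foldid)) {
    foldid <- stratified_foldid(y, n_folds)
  } else if (length(foldid) != length(y) ||
             !all(foldid %in% seq_len(n_folds))) {
    abort("`foldid` must assign every training row to a fold in 1..n_folds.")
  }

  search <- function(Cs, gammas) {
    grid <- expand.grid(C = Cs, gamma = gammas)
    grid$score <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(n_folds), function(f) {
        tr <- foldid != f
        fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = 0:1),
                          kernel = "radial", cost = grid$C[g],
                          gamma = grid$gamma[g], scale = FALSE)
        pred <- predict(fit, x[!tr, , drop = FALSE])
        mean(pred == factor(y[!tr], levels = 0:1))
      }, numeric(1)))
    }, numeric(1))
    grid
  }
  grid <- search(C_grid, gamma_grid)
  best <- grid[which.max(grid$score), ]
  if (refine) {
    fine_C <- best$C * 10^seq(-0.5, 0.5, by = 0.25)
    fine_g <- best$gamma * 10^seq(-0.5, 0.5, by = 0.25)
    grid2 <- search(fine_C, fine_g)
    best2 <- grid2[which.max(grid2$score), ]
    if (best2$score >= best$score) best <- best2
    grid <- rbind(grid, grid2)
  }

  # out-of-fold decision values at the chosen pair, for sigmoid calibration
  dv <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = 0:1),
                      kernel = "radial", cost = best$C, gamma = best$gamma,
                      scale = FALSE)
    dv[!tr] <- attr(predict(fit, x[!tr, , drop = FALSE],
                            decision.values = TRUE), "decision.values")[, 1]
  }
  calib <- suppressWarnings(glm(I(y == 1L) ~ dv, family = binomial()))
  final <- e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                      cost = best$C, gamma = best$gamma, scale = FALSE)
  structure(
    list(kind = "svm", features = features, scaler = scaler, fit = final,
         calibration = coef(calib),
         hyperparameters = list(C = best$C, gamma = best$gamma),
         cv = tibble::as_tibble(grid), cv_score = best$score,
         metric = metric),
    class = "radfuse_model"
  )
}

#' Train a random forest with cross-validated tree count
#'
#' The number of trees is selected from `n_estimators_grid` by stratified
#' `n_folds`-fold cross-validated accuracy; per fold a single forest of
#' `max(grid)` trees is grown and smaller counts are evaluated on its first
#' trees. The class probability of a case is the fraction of trees voting
#' malignant.
#'
#' @param train feature table with a 0/1 `label` column.
#' @param n_estimators_grid tree-count grid (default
#'   `c(10, 100, 1000, 10000)`, one order of magnitude at a time).
#' @param n_folds CV folds (default 10).
#' @param seed integer RNG seed.
#' @return An object of class `radfuse_model` (kind `"rf"`).
#' @export
train_rf <- function(train, n_estimators_grid = c(10, 100, 1000, 10000),
                     n_folds = 10, seed = 1L) {
  check_feature_table(train)
  if (!length(n_estimators_grid)) abort("empty hyperparameter grid.")
  y <- train$label
  if (min(table(y)) < n_folds) abort("need >= `n_folds` rows in each class.")
  features <- feature_columns(train)
  x <- as.matrix(train[features])
  grid <- sort(unique(as.integer(n_estimators_grid)))
  set.seed(seed)
  if (length(grid) > 1L) {
    foldid <- stratified_foldid(y, n_folds)
    votes_ok <- matrix(0, length(y), length(grid))
    for (f in seq_len(n_folds)) {
      tr <- foldid != f
      fit <- randomForest::randomForest(x[tr, , drop = FALSE],
                                        factor(y[tr], levels = 0:1),
                                        ntree = max(grid))
      all_votes <- predict(fit, x[!tr, , drop = FALSE],
                           predict.all = TRUE)$individual == "1"
      for (g in seq_along(grid)) {
        prob <- rowMeans(all_votes[, seq_len(grid[g]), drop = FALSE])
        votes_ok[!tr, g] <- (prob >= 0.5) == (y[!tr] == 1L)
      }
    }
    scores <- colMeans(votes_ok)
    best_n <- grid[which.max(scores)]
  } else {
    best_n <- grid
    scores <- NA_real_
  }
  final <- randomForest::randomForest(x, factor(y, levels = 0:1),
                                      ntree = best_n)
  structure(
    list(kind = "rf", features = features, scaler = NULL, fit = final,
         hyperparameters = list(n_estimators = best_n),
         cv = tibble(n_estimators = grid, score = as.numeric(scores)),
         cv_score = max(scores)),
    class = "radfuse_model"
  )
}

#' @export
print.radfuse_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = " = ", collapse = ", ")
  cat(sprintf("<radfuse_model> %s (%s); %d features\n",
              toupper(x$kind), hp, length(x$features)))
  invisible(x)
}

#' Per-case malignancy probabilities from a trained model
#'
#' Applies the model's training-fitted scaler (SVM) and returns
#' `P(malignant)` per row. The feature schema must match training exactly;
#' missing or extra feature columns raise an error naming them.
#'
#' @param model a `radfuse_model` from [train_svm()] or [train_rf()].
#' @param table feature table with the training feature columns.
#' @return Numeric probability vector in `[0, 1]`.
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "radfuse_model"))
  missing <- setdiff(model$features, names(table))
  extra <- setdiff(feature_columns(table), model$features)
  if (length(missing) || length(extra)) {
    abort(sprintf("feature schema mismatch: missing [%s], extra [%s].",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")))
  }
  x <- as.matrix(table[model$features])
  if (model$kind == "svm") {
    xs <- apply_scaler(x, model$scaler)
    dv <- attr(predict(model$fit, xs, decision.values = TRUE),
               "decision.values")[, 1]
    eta <- model$calibration[1] + model$calibration[2] * dv
    as.numeric(1 / (1 + exp(-eta)))
  } else {
    as.numeric(predict(model$fit, x, type = "prob")[, "1"])
  }
}
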