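# Four-stage feature selection: ICC reproducibility filter -> univariate
# screen -> zero-variance filter -> repeated-CV LASSO.

#' Per-feature intraclass correlation between two raters
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC (ICC(2,1))
#' computed per feature from the two raters' measurements of the same
#' subjects, via the standard ANOVA mean squares. A feature whose total
#' variance is zero has an undefined ICC and is reported as `NA` (it fails
#' any downstream threshold).
#'
#' @param table_a,table_b data frames with identical feature columns and the
#'   same subjects in the same row order (>= 3 rows).
#' @return A tibble with columns `feature` and `icc`.
#' @export
#'
#' @examples
#' pr <- gen_rater_pairs(rater_noise_config(1, 0.3, seed = 7), 30, 5)
#' compute_icc(pr$rater_a, pr$rater_b)
compute_icc <- function(table_a, table_b) {
  if (!identical(sort(names(table_a)), sort(names(table_b)))) {
    abort("the two rater tables must have identical feature columns.")
  }
  if (nrow(table_a) != nrow(table_b)) {
    abort("the two rater tables must have the same subjects (rows).")
  }
  if (nrow(table_a) < 3L) abort("need >= 3 subjects for ICC estimation.")
  feats <- feature_columns(table_a)
  icc <- vapply(feats, function(f) icc21(cbind(table_a[[f]], table_b[[f]])),
                numeric(1))
  tibble(feature = feats, icc = unname(icc))
}

# ICC(2,1) from the two-way ANOVA decomposition of an n x k ratings matrix.
icc21 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  grand <- mean(ratings)
  if (all(ratings == ratings[1])) return(NA_real_)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (denom == 0) return(NA_real_)
  (ms_r - ms_e) / denom
}

#' Filter features by reproducibility
#'
#' Retains exactly the features whose ICC is greater than or equal to the
#' threshold (boundary inclusive); features with undefined (`NA`) ICC fail.
#'
#' @param icc_table output of [compute_icc()].
#' @param threshold minimum acceptable ICC (default 0.8).
#' @return Character vector of retained feature names.
#' @export
icc_filter <- function(icc_table, threshold = 0.8) {
  stopifnot(all(c("feature", "icc") %in% names(icc_table)))
  keep <- icc_table$feature[!is.na(icc_table$icc) &
                              icc_table$icc >= threshold]
  if (!length(keep)) {
    abort("no feature reaches the ICC threshold; the pipeline cannot continue.")
  }
  keep
}

#' Univariate two-group screen
#'
#' Tests every feature for a difference between the benign and malignant
#' groups with both Welch's two-sample t-test and the Mann-Whitney U test.
#' By default a feature survives if it is significant (`p < alpha`) on at
#' least one of the two tests (the lenient reading; the LASSO stage prunes
#' further downstream); `rule = "and"` requires both. Constant features,
#' for which both tests are undefined, are dropped.
#'
#' @param table feature table with a 0/1 `label` column.
#' @param alpha significance level (default 0.05).
#' @param rule `"or"` (default) or `"and"` retention rule.
#' @return A tibble with columns `feature`, `p_t`, `p_mw`, `retained`.
#' @export
univariate_screen <- function(table, alpha = 0.05, rule = c("or", "and")) {
  check_feature_table(table)
  rule <- match.arg(rule)
  if (length(unique(table$label)) < 2L) abort("both classes must be present.")
  feats <- feature_columns(table)
  g0 <- table$label == 0L
  res <- purrr::map_dfr(feats, function(f) {
    x <- table[[f]][g0]
    y <- table[[f]][!g0]
    if (var(c(x, y)) == 0) {
      return(tibble(feature = f, p_t = NA_real_, p_mw = NA_real_,
                    retained = FALSE))
    }
    p_t <- tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
    p_mw <- tryCatch(
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value),
      error = function(e) NA_real_)
    sig <- c(p_t < alpha, p_mw < alpha)
    keep <- if (rule == "or") any(sig, na.rm = TRUE) else all(sig)
    tibble(feature = f, p_t = p_t, p_mw = p_mw,
           retained = isTRUE(keep))
  })
  res
}

#' Remove zero-variance features
#'
#' Drops features whose sample variance is zero (within numerical tolerance
#' `1e-12` after scaling by the squared feature magnitude).
#'
#' @param table feature table.
#' @return Character vector of surviving feature names; a warning is issued
#'   if none survive.
#' @export
variance_filter <- function(table) {
  feats <- feature_columns(table)
  keep <- feats[vapply(feats, function(f) {
    x <- table[[f]]
    v <- var(x)
    scale2 <- max(mean(x^2), 1)
    v > 1e-12 * scale2
  }, logical(1))]
  if (!length(keep)) warn("all features have zero variance.")
  keep
}

# lambda grid: 100 log-spaced points from the data-derived lambda_max
# (smallest penalty with an all-zero solution) down to lambda_max * 1e-4.
lambda_grid_default <- function(x, y, n_points = 100) {
  ybar <- mean(y)
  lambda_max <- max(abs(crossprod(x, y - ybar))) / nrow(x)
  exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = n_points))
}

stratified_foldid <- function(y, n_folds) {
  id <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    id[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
  }
  id
}

#' LASSO feature selection with repeated cross-validation
#'
#' Standardizes the surviving features to zero mean / unit variance, fits
#' the L1-penalized (logistic by default) regression path over a log-spaced
#' lambda grid, chooses the penalty `lambda*` minimizing the mean
#' cross-validated deviance over `n_repeats` independent stratified
#' `n_folds`-fold partitions, refits on all rows at `lambda*`, and returns
#' the nonzero-coefficient features. Coefficients are on the standardized
#' scale.
#'
#' @param table feature table with a 0/1 `label` column; only `features`
#'   (default: all feature columns) enter the fit.
#' @param features candidate feature names (e.g. survivors of earlier
#'   stages).
#' @param n_folds CV folds (default 10).
#' @param n_repeats independent CV repetitions averaged for the deviance
#'   curve (default 50).
#' @param lambda_grid optional decreasing penalty grid; computed from the
#'   data when `NULL`.
#' @param family `"binomial"` (logistic loss, default) or `"gaussian"`
#'   (linear loss on the 0/1 labels).
#' @param seed integer RNG seed for the fold partitions.
#' @return An object of class `lasso_selection`: list with `lambda`
#'   (chosen penalty), `lambda_grid`, `cv_deviance` (mean over repeats),
#'   `selected` (tibble of feature/coefficient), `path` (coefficient matrix
#'   over the grid), `n_nonzero` (per grid point), and `intercept`.
#' @export
lasso_select <- function(table, features = NULL, n_folds = 10,
                         n_repeats = 50, lambda_grid = NULL,
                         family = c("binomial", "gaussian"), seed = 1L) {
  check_feature_table(table)
  family <- match.arg(family)
  features <- features %||% feature_columns(table)
  if (!length(features)) abort("no candidate features supplied.")
  y <- table$label
  if (min(table(y)) < n_folds) {
    abort("`n_folds` exceeds the size of the smaller class.")
  }
  x <- as.matrix(table[features])
  x <- scale(x)
  if (anyNA(x)) abort("constant feature among candidates; run variance_filter first.")
  if (is.null(lambda_grid)) lambda_grid <- lambda_grid_default(x, y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  set.seed(seed)
  cvm <- matrix(0, n_repeats, length(lambda_grid))
  for (r in seq_len(n_repeats)) {
    foldid <- stratified_foldid(y, n_folds)
    cv <- glmnet::cv.glmnet(x, y, family = family, lambda = lambda_grid,
                            foldid = foldid, type.measure = "deviance",
                            standardize = FALSE)
    cvm[r, ] <- cv$cvm[match(lambda_grid, cv$lambda)]
  }
  mean_dev <- colMeans(cvm)
  lambda_star <- lambda_grid[which.min(mean_dev)]

  fit <- glmnet::glmnet(x, y, family = family, lambda = lambda_grid,
                        standardize = FALSE)
  beta <- as.matrix(fit$beta)
  b_star <- beta[, which.min(abs(fit$lambda - lambda_star))]
  sel <- b_star[b_star != 0]
  if (!length(sel)) {
    warn("the LASSO solution at lambda* is all-zero; no features selected.")
  }
  structure(
    list(lambda = lambda_star, lambda_grid = lambda_grid,
         cv_deviance = mean_dev,
         selected = tibble(feature = names(sel), coefficient = unname(sel)),
         path = beta, n_nonzero = colSums(beta != 0),
         intercept = fit$a0[which.min(abs(fit$lambda - lambda_star))],
         family = family, n_repeats = n_repeats, n_folds = n_folds),
    class = "lasso_selection"
  )
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection> lambda = %.6g, %d features selected (%s loss, %d x %d-fold CV)\n",
              x$lambda, nrow(x$selected), x$family, x$n_repeats, x$n_folds))
  invisible(x)
}

#' Run the full selection chain
#'
#' Applies the fixed stage order: ICC reproducibility filter (when rater
#' tables are supplied), univariate screen, zero-variance filter, then
#' repeated-CV LASSO. Each stage's survivor set is a subset of its input.
#'
#' @param table feature table with a 0/1 `label` column.
#' @param rater_pairs optional list with `rater_a`/`rater_b` tables (same
#'   feature columns) for the ICC stage; `NULL` skips it.
#' @param icc_threshold minimum ICC (default 0.8).
#' @param alpha screen significance level.
#' @param screen_rule `"or"` or `"and"` retention rule for the screen.
#' @inheritParams lasso_select
#' @return An object of class `selection_report`: list with `icc`
#'   (tibble or `NULL`), `icc_survivors`, `screen` (tibble),
#'   `screen_survivors`, `variance_survivors`, and `lasso`
#'   (a `lasso_selection`).
#' @export
select_features <- function(table, rater_pairs = NULL, icc_threshold = 0.8,
                            alpha = 0.05, screen_rule = "or", n_folds = 10,
                            n_repeats = 50, lambda_grid = NULL,
                            family = "binomial", seed = 1L) {
  check_feature_table(table)
  candidates <- feature_columns(table)
  icc_tab <- NULL
  if (!is.null(rater_pairs)) {
    icc_tab <- compute_icc(rater_pairs$rater_a, rater_pairs$rater_b)
    keep <- icc_filter(icc_tab, icc_threshold)
    candidates <- intersect(candidates, keep)
  }
  icc_survivors <- candidates
  scr <- univariate_screen(table[c(candidates, "label")], alpha = alpha,
                           rule = screen_rule)
  candidates <- intersect(candidates, scr$feature[scr$retained])
  screen_survivors <- candidates
  if (!length(candidates)) abort("no features survive the univariate screen.")
  candidates <- intersect(candidates, variance_filter(table[candidates]))
  if (!length(candidates)) abort("no features survive the variance filter.")
  lasso <- lasso_select(table, features = candidates, n_folds = n_folds,
                        n_repeats = n_repeats, lambda_grid = lambda_grid,
                        family = family, seed = seed)
  structure(
    list(icc = icc_tab, icc_survivors = icc_survivors,
         screen = scr, screen_survivors = screen_survivors,
         variance_survivors = candidates, lasso = lasso),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  if (!is.null(x$icc)) {
    cat(sprintf("  ICC filter: %d / %d features retained\n",
                length(x$icc_survivors), nrow(x$icc)))
  }
  cat(sprintf("  screen: %d survivors; variance filter: %d; LASSO: %d selected at lambda = %.4g\n",
              length(x$screen_survivors), length(x$variance_survivors),
              nrow(x$lasso$selected), x$lasso$lambda))
  invisible(x)
}

#' Spearman correlation matrix of selected features
#'
#' @param table feature table restricted (or restrictable via `features`)
#'   to the selected features; needs >= 2 features and >= 3 rows.
#' @param features optional feature names to use.
#' @return Symmetric correlation matrix with unit diagonal; entries for
#'   constant features are `NA`.
#' @export
spearman_matrix <- function(table, features = NULL) {
  features <- features %||% feature_columns(table)
  if (length(features) < 2L) abort("need >= 2 features.")
  if (nrow(table) < 3L) abort("need >= 3 rows.")
  x <- as.matrix(table[features])
  constant <- apply(x, 2, function(v) var(v) == 0)
  m <- suppressWarnings(stats::cor(x, method = "spearman"))
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- ifelse(constant, NA_real_, 1)
  m
}
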