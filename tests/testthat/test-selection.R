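test_that("ICC is 1 for identical raters and ~0 for permuted subjects", {
  set.seed(1)
  tab <- tibble::tibble(f1 = rnorm(30), f2 = runif(30))
  expect_equal(unname(compute_icc(tab, tab)$icc), c(1, 1), tolerance = 1e-12)
  perm <- tab[sample(30), ]
  icc_perm <- compute_icc(
    tibble::tibble(f1 = rnorm(500)),
    tibble::tibble(f1 = rnorm(500)))$icc
  expect_lt(abs(icc_perm), 0.15)
  expect_error(compute_icc(tab[1:2, ], tab[1:2, ]), ">= 3")
})

test_that("ICC estimate recovers the variance-ratio ground truth", {
  pr <- gen_rater_pairs(rater_noise_config(1, 1, seed = 13),
                        n_subjects = 500, n_features = 10)
  icc <- compute_icc(pr$rater_a, pr$rater_b)$icc
  expect_equal(mean(icc), 0.5, tolerance = 0.1)
  expect_true(all(abs(icc - 0.5) < 0.15))
  # a constant feature has undefined ICC
  ca <- tibble::tibble(f1 = rep(1, 10))
  expect_true(is.na(compute_icc(ca, ca)$icc))
})

test_that("the ICC filter is boundary-inclusive at the threshold", {
  icc_tab <- tibble::tibble(feature = c("a", "b", "c", "d"),
                            icc = c(0.80, 0.79, 0.95, NA))
  expect_equal(icc_filter(icc_tab, 0.8), c("a", "c"))
  expect_error(icc_filter(tibble::tibble(feature = "a", icc = 0.1), 0.8),
               "no feature")
})

test_that("the univariate screen keeps separated features, drops constants", {
  tab <- gen_feature_table(cohort_config(n_benign = 100, n_malignant = 100,
                                         p_features = 30, k_informative = 8,
                                         effect_size = 2, seed = 5))
  scr <- univariate_screen(tab)
  inf <- attr(tab, "informative_features")
  expect_true(all(scr$retained[scr$feature %in% inf]))
  # constant feature is dropped with both tests undefined
  tab$const <- 1
  scr2 <- univariate_screen(tab)
  row <- scr2[scr2$feature == "const", ]
  expect_false(row$retained)
  expect_true(is.na(row$p_t))
  # alpha = 1 keeps every non-constant feature
  scr3 <- univariate_screen(tab, alpha = 1)
  expect_true(all(scr3$retained[scr3$feature != "const"]))
  # strict AND rule is never more permissive than OR
  scr_and <- univariate_screen(tab, rule = "and")
  expect_true(all(!scr_and$retained | scr$retained))
})

test_that("null features are retained at about the alpha rate", {
  kept <- unlist(lapply(1:15, function(s) {
    tab <- gen_feature_table(cohort_config(n_benign = 100, n_malignant = 100,
                                           p_features = 40, k_informative = 0,
                                           effect_size = 0, block_rho = 0,
                                           seed = 100 + s))
    scr <- univariate_screen(tab)
    scr$retained
  }))
  expect_gt(mean(kept), 0.02)
  expect_lt(mean(kept), 0.15)  # OR of two correlated tests, slightly > alpha
})

test_that("the variance filter removes exactly the constant columns", {
  tab <- tibble::tibble(a = rep(1, 10), b = c(rep(0, 9), 1e-3),
                        c = rnorm(10), label = rep(0:1, 5))
  expect_setequal(variance_filter(tab), c("b", "c"))
  expect_warning(variance_filter(tibble::tibble(a = rep(2, 5))), "zero variance")
})

test_that("full shrinkage selects nothing; path support is monotone", {
  tab <- gen_feature_table(cohort_config(n_benign = 50, n_malignant = 50,
                                         p_features = 20, k_informative = 5,
                                         effect_size = 1, seed = 9))
  x <- scale(as.matrix(tab[feature_columns(tab)]))
  lam_max <- max(abs(crossprod(x, tab$label - mean(tab$label)))) / nrow(x)
  expect_warning(
    lasso_select(tab, n_repeats = 1, n_folds = 5,
                 lambda_grid = c(10 * lam_max, 5 * lam_max), seed = 1),
    "all-zero")
  sel <- suppressWarnings(
    lasso_select(tab, n_repeats = 1, n_folds = 5,
                 lambda_grid = c(10 * lam_max, 5 * lam_max), seed = 1))
  expect_equal(nrow(sel$selected), 0)

  full <- lasso_select(tab, n_repeats = 2, n_folds = 5, seed = 1)
  # support grows as the penalty relaxes; the exact active set may shed a
  # feature transiently (a real property of the L1 path), so check the trend
  nz <- full$n_nonzero  # grid is stored decreasing in lambda
  expect_true(all(diff(nz) >= -1))
  expect_gte(stats::cor(seq_along(nz), as.numeric(nz), method = "spearman"),
             0.9)
  expect_equal(nz[[1]], 0)
  expect_true(all(full$selected$coefficient != 0))
})

test_that("a vanishing penalty recovers the unpenalized logistic fit", {
  set.seed(4)
  n <- 400
  tab <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  eta <- 0.8 * tab$x1 - 0.5 * tab$x2
  tab$label <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  x <- scale(as.matrix(tab[c("x1", "x2")]))
  ref <- glm(tab$label ~ x, family = binomial())
  sel <- lasso_select(tab, n_repeats = 1, n_folds = 5,
                      lambda_grid = c(0.1, 1e-3, 1e-6), seed = 2)
  fit0 <- glmnet::glmnet(x, tab$label, family = "binomial",
                         lambda = c(0.1, 1e-3, 1e-6), standardize = FALSE)
  b <- as.matrix(fit0$beta)[, 3]
  expect_equal(unname(b), unname(coef(ref)[-1]), tolerance = 1e-4)
})

test_that("informative-feature recovery improves with effect size", {
  recovery <- vapply(c(0.25, 1.0, 2.0), function(es) {
    hits <- vapply(1:3, function(s) {
      tab <- gen_feature_table(cohort_config(n_benign = 75, n_malignant = 75,
                                             p_features = 40,
                                             k_informative = 6,
                                             effect_size = es,
                                             block_rho = 0.3,
                                             seed = 200 + s))
      sel <- suppressWarnings(
        lasso_select(tab, n_repeats = 2, n_folds = 5, seed = s))
      mean(attr(tab, "informative_features") %in% sel$selected$feature)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(recovery[3] >= recovery[1])
  expect_gt(recovery[3], 0.9)
})

test_that("the selection chain keeps nested survivor sets", {
  tab <- gen_feature_table(cohort_config(n_benign = 60, n_malignant = 60,
                                         p_features = 30, k_informative = 6,
                                         effect_size = 1.5, seed = 31))
  pr <- gen_rater_pairs(rater_noise_config(1, 0.3, seed = 2),
                        n_subjects = 30, n_features = 30)
  names(pr$rater_a) <- names(pr$rater_b) <- feature_columns(tab)
  rep <- select_features(tab, rater_pairs = pr, n_repeats = 2, n_folds = 5,
                         seed = 3)
  expect_true(all(rep$screen_survivors %in% rep$icc_survivors))
  expect_true(all(rep$variance_survivors %in% rep$screen_survivors))
  expect_true(all(rep$lasso$selected$feature %in% rep$variance_survivors))
  g <- glance(rep)
  expect_equal(g$n_selected, nrow(tidy(rep)))
})

test_that("Spearman correlation respects ranks and the hand-computed case", {
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  m <- spearman_matrix(tibble::tibble(x = x, y = y))
  expect_equal(m["x", "y"], -0.5)
  expect_equal(diag(m), c(x = 1, y = 1))
  # rank invariance under monotone transforms
  set.seed(8)
  z <- rnorm(20)
  m2 <- spearman_matrix(tibble::tibble(a = z, b = exp(z)))
  expect_equal(m2["a", "b"], 1)
  # constant feature reported missing
  m3 <- spearman_matrix(tibble::tibble(a = z, b = rep(1, 20)))
  expect_true(is.na(m3["a", "b"]))
  expect_error(spearman_matrix(tibble::tibble(a = z)), ">= 2")
})
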