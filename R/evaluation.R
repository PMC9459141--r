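# Diagnostic-performance evaluation: ROC/AUC, exact binomial confidence
# intervals for sensitivity/specificity/precision, Cohen's kappa, and the
# paired DeLong test for comparing correlated AUCs.

#' ROC curve and AUC
#'
#' AUC is computed through the Mann-Whitney U identity (ties counted one
#' half); ROC points are returned at every distinct score threshold.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels 0/1 labels.
#' @return An object of class `radfuse_roc`: list with `auc` and `roc`, a
#'   tibble of `threshold`, `fpr`, `tpr`.
#' @export
#'
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc  # 0.75
roc_auc <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels)) abort("length mismatch.")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present.")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    calls <- scores >= t
    tibble(threshold = t,
           fpr = sum(calls & labels == 0L) / n0,
           tpr = sum(calls & labels == 1L) / n1)
  })
  structure(list(auc = auc, roc = pts, n_pos = n1, n_neg = n0),
            class = "radfuse_roc")
}

#' @export
print.radfuse_roc <- function(x, ...) {
  cat(sprintf("<radfuse_roc> AUC = %.4f (%d malignant / %d benign)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  c(lower = if (x == 0) 0 else qbeta(a, x, n - x + 1),
    upper = if (x == n) 1 else qbeta(1 - a, x + 1, n - x))
}

#' Sensitivity, specificity and precision with exact confidence intervals
#'
#' Point estimates from the 2x2 table of calls against labels, with 95%
#' Clopper-Pearson exact binomial intervals by default (`ci = "wilson"`
#' gives score intervals). Precision is undefined (reported `NA`) when no
#' positive calls are made.
#'
#' @param calls 0/1 predicted calls.
#' @param labels 0/1 reference labels.
#' @param level confidence level (default 0.95).
#' @param ci `"exact"` (Clopper-Pearson, default) or `"wilson"`.
#' @return A tibble with columns `metric`, `estimate`, `lower`, `upper`,
#'   `x`, `n`.
#' @export
binary_metrics <- function(calls, labels, level = 0.95,
                           ci = c("exact", "wilson")) {
  ci <- match.arg(ci)
  calls <- check_binary(calls, "calls")
  labels <- check_binary(labels, "labels")
  if (length(calls) != length(labels)) abort("length mismatch.")
  if (length(unique(labels)) < 2L) abort("both classes must be present.")
  tp <- sum(calls == 1L & labels == 1L)
  fn <- sum(calls == 0L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  tn <- sum(calls == 0L & labels == 0L)
  one <- function(metric, x, n) {
    if (n == 0L) {
      return(tibble(metric = metric, estimate = NA_real_, lower = NA_real_,
                    upper = NA_real_, x = x, n = n))
    }
    iv <- if (ci == "exact") clopper_pearson(x, n, level) else {
      w <- suppressWarnings(stats::prop.test(x, n, conf.level = level,
                                             correct = FALSE)$conf.int)
      c(lower = w[1], upper = w[2])
    }
    tibble(metric = metric, estimate = x / n,
           lower = iv[["lower"]], upper = iv[["upper"]], x = x, n = n)
  }
  dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("precision", tp, tp + fp)
  )
}

#' Cohen's kappa of calls against labels
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the 2x2
#' table. When expected agreement is 1 (both margins degenerate), kappa is
#' defined as 0 with a warning.
#'
#' @inheritParams binary_metrics
#' @return Single numeric value in `[-1, 1]`.
#' @export
cohens_kappa <- function(calls, labels) {
  calls <- check_binary(calls, "calls")
  labels <- check_binary(labels, "labels")
  n <- length(labels)
  po <- mean(calls == labels)
  pe <- mean(calls == 1L) * mean(labels == 1L) +
    mean(calls == 0L) * mean(labels == 0L)
  if (pe == 1) {
    warn("expected agreement is 1; kappa defined as 0.")
    return(0)
  }
  (po - pe) / (1 - pe)
}

# DeLong placements: for each case X_i, the fraction of controls it beats
# (ties half), and symmetrically for controls.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  r_x <- rank(x)
  r_y <- rank(y)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors on the same cases via the DeLong
#' placement-covariance method, returning the two-sided p-value. A
#' label-permutation test (`method = "permutation"`) is provided for
#' comparisons where one arm is a binary verdict and the asymptotic
#' normal approximation is doubtful.
#'
#' @param scores_a,scores_b paired score vectors on identical cases.
#' @param labels 0/1 labels.
#' @param method `"delong"` (default) or `"permutation"` (randomly swaps
#'   the two arms per case under the null of exchangeable scores).
#' @param n_perm permutations for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return A tibble with `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        method = c("delong", "permutation"),
                        n_perm = 2000, seed = 1L) {
  method <- match.arg(method)
  labels <- check_binary(labels, "labels")
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    abort("scores and labels must be paired (equal lengths).")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  delta <- pa$auc - pb$auc
  if (method == "delong") {
    m <- length(pa$v10)
    n <- length(pa$v01)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    if (!is.finite(v) || v <= 0) {
      if (delta == 0) {
        p <- 1
      } else {
        warn("degenerate DeLong variance; p-value undefined.")
        p <- NA_real_
      }
    } else {
      p <- 2 * pnorm(-abs(delta) / sqrt(v))
    }
  } else {
    set.seed(seed)
    obs <- abs(delta)
    null <- vapply(seq_len(n_perm), function(i) {
      swap <- runif(length(labels)) < 0.5
      a <- ifelse(swap, scores_b, scores_a)
      b <- ifelse(swap, scores_a, scores_b)
      abs(delong_placements(a, labels)$auc - delong_placements(b, labels)$auc)
    }, numeric(1))
    p <- (1 + sum(null >= obs)) / (n_perm + 1)
  }
  tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta, p_value = p)
}

#' Full diagnostic report for one prediction arm
#'
#' Bundles AUC, the thresholded binary metrics with exact CIs, and Cohen's
#' kappa for one set of scores (or binary calls) against the reference
#' labels.
#'
#' @param scores numeric scores or binary calls.
#' @param labels 0/1 labels.
#' @param threshold calling threshold applied to `scores` (default 0.5,
#'   ties to malignant).
#' @param arm optional arm name carried into the output.
#' @inheritParams binary_metrics
#' @return An object of class `eval_report`: list with `arm`, `auc`,
#'   `roc` (tibble), `metrics` (tibble), `kappa`, `threshold`.
#' @export
evaluate_arm <- function(scores, labels, threshold = 0.5, arm = "model",
                         level = 0.95, ci = "exact") {
  roc <- roc_auc(scores, labels)
  calls <- as.integer(scores >= threshold)
  structure(
    list(arm = arm, auc = roc$auc, roc = roc$roc,
         metrics = binary_metrics(calls, labels, level = level, ci = ci),
         kappa = cohens_kappa(calls, labels), threshold = threshold),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<eval_report> %s: AUC %.3f | sens %.2f (%.2f-%.2f) | spec %.2f (%.2f-%.2f) | prec %.2f | kappa %.3f\n",
              x$arm, x$auc,
              m$estimate[1], m$lower[1], m$upper[1],
              m$estimate[2], m$lower[2], m$upper[2],
              m$estimate[3], x$kappa))
  invisible(x)
}

# Brown-Forsythe variance-homogeneity test (Levene with group medians).
brown_forsythe <- function(x, g) {
  g <- factor(g)
  z <- abs(x - stats::ave(x, g, FUN = median))
  stats::oneway.test(z ~ g, var.equal = TRUE)$p.value
}

#' Group comparison summary for a cohort table
#'
#' For each continuous variable, normality in each group is checked with
#' Shapiro-Wilk; normal variables are compared with Welch's t-test,
#' non-normal ones with the Mann-Whitney U test (variance homogeneity is
#' reported via the Brown-Forsythe/Levene statistic but does not gate the
#' choice). Categorical (factor/character/logical) variables are compared
#' with the chi-square test.
#'
#' @param table data frame of per-patient variables.
#' @param group name of the grouping column (two or more groups).
#' @return A tibble with `variable`, `type`, `test`, `p_value` and group
#'   summaries (`median (SD)` for continuous, counts for categorical).
#' @export
cohort_summary <- function(table, group) {
  if (!group %in% names(table)) abort(sprintf("no column `%s`.", group))
  g <- factor(table[[group]])
  if (any(table(g) == 0L) || nlevels(g) < 2L) {
    abort("each group must be non-empty and >= 2 groups present.")
  }
  vars <- setdiff(names(table), group)
  purrr::map_dfr(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      if (var(x) == 0) {
        return(tibble(variable = v, type = "continuous", test = "none",
                      p_value = 1,
                      summary = paste0(median(x), " (0)")))
      }
      normal <- all(tapply(x, g, function(xx) {
        if (length(unique(xx)) < 3L || length(xx) < 3L) return(FALSE)
        shapiro.test(xx)$p.value >= 0.05
      }))
      if (normal && nlevels(g) == 2L) {
        p <- t.test(x ~ g)$p.value
        test <- "t"
      } else if (nlevels(g) == 2L) {
        p <- suppressWarnings(wilcox.test(x ~ g, exact = FALSE)$p.value)
        test <- "mann-whitney"
      } else {
        p <- stats::kruskal.test(x ~ g)$p.value
        test <- "kruskal-wallis"
      }
      tibble(variable = v, type = "continuous", test = test, p_value = p,
             summary = paste(sprintf("%.3g (%.3g)", tapply(x, g, median),
                                     tapply(x, g, sd)), collapse = " vs "))
    } else {
      tab <- table(x, g)
      p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      tibble(variable = v, type = "categorical", test = "chi-square",
             p_value = p,
             summary = paste(apply(tab, 2, paste, collapse = "/"),
                             collapse = " vs "))
    }
  })
}
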