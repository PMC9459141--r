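# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a LASSO selection
#'
#' @param x a `lasso_selection` from [lasso_select()].
#' @param ... unused.
#' @return A tibble of selected features and their (standardized-scale)
#'   coefficients.
#' @export
tidy.lasso_selection <- function(x, ...) {
  x$selected
}

#' @rdname tidy.lasso_selection
#' @export
glance.lasso_selection <- function(x, ...) {
  tibble(lambda = x$lambda, n_selected = nrow(x$selected),
         min_cv_deviance = min(x$cv_deviance),
         n_repeats = x$n_repeats, n_folds = x$n_folds, family = x$family)
}

#' Tidy a selection report
#'
#' @param x a `selection_report` from [select_features()].
#' @param ... unused.
#' @return Selected features with coefficients and the per-stage survival
#'   of each.
#' @export
tidy.selection_report <- function(x, ...) {
  x$lasso$selected
}

#' @rdname tidy.selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble(n_icc_survivors = length(x$icc_survivors),
         n_screen_survivors = length(x$screen_survivors),
         n_variance_survivors = length(x$variance_survivors),
         n_selected = nrow(x$lasso$selected),
         lambda = x$lasso$lambda)
}

#' Tidy an evaluation report
#'
#' @param x an `eval_report` from [evaluate_arm()].
#' @param ... unused.
#' @return A tibble with one row per metric (AUC, sensitivity, specificity,
#'   precision, kappa) and its confidence bounds where defined.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "auc", estimate = x$auc,
           lower = NA_real_, upper = NA_real_),
    x$metrics[c("metric", "estimate", "lower", "upper")],
    tibble(metric = "kappa", estimate = x$kappa,
           lower = NA_real_, upper = NA_real_)
  ) |>
    dplyr::mutate(arm = x$arm, .before = 1)
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  m <- x$metrics
  tibble(arm = x$arm, auc = x$auc, sensitivity = m$estimate[1],
         specificity = m$estimate[2], precision = m$estimate[3],
         kappa = x$kappa, threshold = x$threshold)
}

#' Glance at a trained classifier
#'
#' @param x a `radfuse_model`.
#' @param ... unused.
#' @return One-row tibble with the model kind, chosen hyperparameters and
#'   CV score.
#' @export
glance.radfuse_model <- function(x, ...) {
  dplyr::bind_cols(tibble(kind = x$kind),
                   as_tibble(x$hyperparameters),
                   tibble(cv_score = x$cv_score,
                          n_features = length(x$features)))
}

#' Plot an ROC curve
#'
#' @param object a `radfuse_roc` from [roc_auc()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.radfuse_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the LASSO cross-validation curve and coefficient path
#'
#' @param object a `lasso_selection` from [lasso_select()].
#' @param type `"cv"` (mean CV deviance over lambda) or `"path"`
#'   (coefficient solution path).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lasso_selection <- function(object, type = c("cv", "path"), ...) {
  type <- match.arg(type)
  if (type == "cv") {
    d <- tibble(lambda = object$lambda_grid, deviance = object$cv_deviance)
    ggplot2::ggplot(d, ggplot2::aes(log(.data$lambda), .data$deviance)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2) +
      ggplot2::labs(x = "log(lambda)", y = "Mean CV deviance") +
      ggplot2::theme_minimal()
  } else {
    d <- as_tibble(as.matrix(object$path)) |>
      dplyr::mutate(feature = rownames(object$path)) |>
      tidyr::pivot_longer(-"feature", names_to = "step",
                          values_to = "coefficient") |>
      dplyr::mutate(lambda = rep(object$lambda_grid,
                                 times = nrow(object$path)))
    ggplot2::ggplot(d, ggplot2::aes(log(.data$lambda), .data$coefficient,
                                    group = .data$feature)) +
      ggplot2::geom_line(alpha = 0.5) +
      ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2) +
      ggplot2::labs(x = "log(lambda)", y = "Standardized coefficient") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param m matrix from [spearman_matrix()].
#' @return A ggplot tile map.
#' @export
plot_spearman <- function(m) {
  d <- as_tibble(m, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "rho") |>
    dplyr::mutate(row = factor(.data$row, levels = rownames(m)),
                  col = factor(.data$col, levels = colnames(m)))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
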