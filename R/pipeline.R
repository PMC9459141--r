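# End-to-end orchestration: synthesize (or load) -> select -> train ->
# fuse -> evaluate, with one global seed fanned out to per-stage seeds and
# JSON reports written to a run directory.

# Deterministic per-stage seeds derived from the global seed. Offsets are
# fixed so a stage can be rerun independently with unchanged randomness.
stage_seeds <- function(seed) {
  offsets <- c(synth = 1L, readers_jr = 2L, readers_sr = 3L, raters = 4L,
               split = 5L, select = 6L, svm = 7L, rf = 8L)
  as.list((as.integer(seed) * 131L + offsets) %% .Machine$integer.max)
}

#' Pipeline configuration
#'
#' Validated bundle of per-stage settings for [run_pipeline()]. The data
#' source is either a synthetic cohort configuration or a path to a feature
#' table CSV (with `label`, `reader_jr`, `reader_sr` columns).
#'
#' @param cohort a [cohort_config()] for synthetic data, or `NULL` when
#'   `table_path` is given.
#' @param table_path optional CSV path of a precomputed feature table.
#' @param reader_junior,reader_senior [reader_profile()]s used to simulate
#'   verdicts when the table does not carry them.
#' @param rater_noise a [rater_noise_config()] for the reproducibility
#'   stage, or `NULL` to skip the ICC filter.
#' @param test_fraction,val_fraction split fractions (see
#'   [split_cohort()]).
#' @param icc_threshold,alpha,screen_rule,n_repeats selection settings
#'   (see [select_features()]).
#' @param C_grid,gamma_grid,n_estimators_grid classifier grids.
#' @param cv_folds cross-validation folds for selection and tuning.
#' @param fusion_threshold calling threshold on fused scores.
#' @param seed global integer seed fanned out to per-stage seeds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            table_path = NULL,
                            reader_junior = reader_profile(0.63, 0.67, "junior"),
                            reader_senior = reader_profile(0.63, 0.87, "senior"),
                            rater_noise = rater_noise_config(),
                            test_fraction = 0.25, val_fraction = 0.2,
                            icc_threshold = 0.8, alpha = 0.05,
                            screen_rule = "or", n_repeats = 10,
                            C_grid = 10^(-2:3), gamma_grid = 10^(-4:1),
                            n_estimators_grid = c(10, 100, 1000),
                            cv_folds = 10, fusion_threshold = 0.5,
                            seed = 1L) {
  if (!is.null(table_path) && !file.exists(table_path)) {
    abort(sprintf("input path does not exist: %s", table_path))
  }
  if (is.null(table_path)) stopifnot(inherits(cohort, "cohort_config"))
  check_count(seed, "seed", min = 0L)
  structure(
    list(cohort = cohort, table_path = table_path,
         reader_junior = reader_junior, reader_senior = reader_senior,
         rater_noise = rater_noise, test_fraction = test_fraction,
         val_fraction = val_fraction, icc_threshold = icc_threshold,
         alpha = alpha, screen_rule = screen_rule, n_repeats = n_repeats,
         C_grid = C_grid, gamma_grid = gamma_grid,
         n_estimators_grid = n_estimators_grid, cv_folds = cv_folds,
         fusion_threshold = fusion_threshold, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in study order — synthesize or load the cohort,
#' simulate reader verdicts, ICC reproducibility filter, univariate screen,
#' variance filter, repeated-CV LASSO, SVM and RF training on the training
#' split, probability prediction, confidence-gated fusion with each reader
#' tier, and diagnostic evaluation of all six arms (SVM, RF, reader-JR,
#' reader-SR, SVM+RF+JR, SVM+RF+SR) on the validation and test splits.
#' Reports (`selection.json`, `models.json`, `evaluation.json`,
#' `fusion_validation.csv`, `fusion_test.csv`, `manifest.json`) are written
#' to `outdir`. Identical config and seed produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return Invisibly, a list with the in-memory `selection`, `models`,
#'   `evaluation` tibble and the `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # stage: cohort ------------------------------------------------------------
  if (!is.null(config$table_path)) {
    tab <- read_feature_table(config$table_path)
  } else {
    cohort <- config$cohort
    cohort$seed <- seeds$synth
    tab <- gen_feature_table(cohort)
  }
  if (!"reader_jr" %in% names(tab)) {
    tab$reader_jr <- gen_reader_calls(tab$label, config$reader_junior,
                                      seed = seeds$readers_jr)
  }
  if (!"reader_sr" %in% names(tab)) {
    tab$reader_sr <- gen_reader_calls(tab$label, config$reader_senior,
                                      seed = seeds$readers_sr)
  }

  # stage: split ---------------------------------------------------------------
  splits <- split_cohort(tab, config$test_fraction, config$val_fraction,
                         seed = seeds$split)
  pool <- dplyr::bind_rows(splits$train, splits$validation)  # selection pool

  # stage: selection -----------------------------------------------------------
  rater_pairs <- NULL
  if (!is.null(config$rater_noise)) {
    rn <- config$rater_noise
    rn$seed <- seeds$raters
    rater_pairs <- gen_rater_pairs(rn, n_subjects = 30,
                                   n_features = length(feature_columns(tab)))
    names(rater_pairs$rater_a) <- feature_columns(tab)
    names(rater_pairs$rater_b) <- feature_columns(tab)
  }
  selection <- select_features(pool, rater_pairs = rater_pairs,
                               icc_threshold = config$icc_threshold,
                               alpha = config$alpha,
                               screen_rule = config$screen_rule,
                               n_folds = config$cv_folds,
                               n_repeats = config$n_repeats,
                               seed = seeds$select)
  selected <- selection$lasso$selected$feature
  if (!length(selected)) abort("selection stage returned no features.")

  keep_cols <- c(selected, "label")
  train <- splits$train[keep_cols]
  arms_input <- list(validation = splits$validation, test = splits$test)

  # stage: classifiers ---------------------------------------------------------
  svm <- train_svm(train, C_grid = config$C_grid,
                   gamma_grid = config$gamma_grid,
                   n_folds = config$cv_folds, seed = seeds$svm)
  rf <- train_rf(train, n_estimators_grid = config$n_estimators_grid,
                 n_folds = config$cv_folds, seed = seeds$rf)

  # stage: fusion + evaluation -------------------------------------------------
  evaluation <- list()
  for (split_name in names(arms_input)) {
    d <- arms_input[[split_name]]
    p_svm <- predict_proba(svm, d[selected])
    p_rf <- predict_proba(rf, d[selected])
    fused_jr <- fuse_cohort(p_svm, p_rf, d$reader_jr,
                            threshold = config$fusion_threshold)
    fused_sr <- fuse_cohort(p_svm, p_rf, d$reader_sr,
                            threshold = config$fusion_threshold)
    utils::write.csv(fused_sr, file.path(outdir,
                                         sprintf("fusion_%s.csv", split_name)),
                     row.names = FALSE)
    arms <- list(
      svm = p_svm, rf = p_rf,
      reader_jr = as.numeric(d$reader_jr),
      reader_sr = as.numeric(d$reader_sr),
      svm_rf_jr = fused_jr$s_mlad, svm_rf_sr = fused_sr$s_mlad
    )
    evaluation[[split_name]] <- purrr::imap_dfr(arms, function(sc, nm) {
      rep <- evaluate_arm(sc, d$label, threshold = config$fusion_threshold,
                          arm = nm)
      m <- rep$metrics
      tibble(split = split_name, arm = nm, auc = rep$auc,
             sensitivity = m$estimate[1], sens_lower = m$lower[1],
             sens_upper = m$upper[1],
             specificity = m$estimate[2], spec_lower = m$lower[2],
             spec_upper = m$upper[2],
             precision = m$estimate[3], prec_lower = m$lower[3],
             prec_upper = m$upper[3],
             kappa = rep$kappa)
    })
    cmp <- compare_auc(arms$svm_rf_sr, arms$svm, d$label)
    evaluation[[split_name]]$p_vs_svm <- NA_real_
    evaluation[[split_name]]$p_vs_svm[
      evaluation[[split_name]]$arm == "svm_rf_sr"] <- cmp$p_value
  }
  eval_tab <- dplyr::bind_rows(evaluation)

  # reports --------------------------------------------------------------------
  write_json_report(list(
    lambda = selection$lasso$lambda,
    n_repeats = selection$lasso$n_repeats,
    icc_survivors = length(selection$icc_survivors),
    screen_survivors = length(selection$screen_survivors),
    variance_survivors = length(selection$variance_survivors),
    selected = selection$lasso$selected
  ), file.path(outdir, "selection.json"))
  write_json_report(list(
    svm = c(svm$hyperparameters, list(cv_score = svm$cv_score)),
    rf = c(rf$hyperparameters, list(cv_score = rf$cv_score))
  ), file.path(outdir, "models.json"))
  write_json_report(eval_tab, file.path(outdir, "evaluation.json"))
  write_json_report(list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("radfuse")),
    seed = config$seed,
    stage_seeds = seeds,
    config_hash = rlang::hash(config)
  ), file.path(outdir, "manifest.json"))

  invisible(list(selection = selection, models = list(svm = svm, rf = rf),
                 evaluation = eval_tab, outdir = outdir))
}

#' Read and write feature tables as CSV
#'
#' The CSV has a header row of feature names, one row per patient, and
#' final columns `label` (0 benign / 1 malignant) and optionally
#' `reader_jr` / `reader_sr`. Round trip is the identity up to float
#' formatting at 17 significant digits.
#'
#' @param table a feature table (tibble).
#' @param path CSV file path.
#' @param require_label error if the `label` column is absent on read.
#' @return `read_feature_table()` returns a tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table, require_label = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = ","), con)
  body <- apply(as.data.frame(table), 1, function(row) {
    paste(vapply(row, function(v) {
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, character(1)), collapse = ",")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, require_label = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicate column header `%s` in %s.",
                  names(raw)[duplicated(names(raw))][1], path))
  }
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]])) {
      conv <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(is.na(conv) & !is.na(raw[[j]]))
      if (length(bad)) {
        abort(sprintf("non-numeric cell at row %d, column `%s`.",
                      bad[1], names(raw)[j]))
      }
      raw[[j]] <- conv
    }
  }
  tab <- as_tibble(raw)
  if (require_label) {
    if (!"label" %in% names(tab)) abort("missing `label` column.")
    check_binary(tab$label, "label")
    tab$label <- as.integer(tab$label)
  }
  tab
}

#' Validate a feature table's columns against the descriptor catalog
#'
#' Checks that every feature column names a descriptor in the default
#' catalog (`<image_type>_<class>_<name>` keys).
#'
#' @param table a feature table.
#' @return Invisibly `TRUE`; errors naming the first unknown column.
#' @export
validate_against_catalog <- function(table) {
  feats <- feature_columns(table)
  known <- catalog_features()$feature
  bad <- setdiff(feats, known)
  if (length(bad)) {
    abort(sprintf("column `%s` is not a catalog descriptor.", bad[1]))
  }
  invisible(TRUE)
}
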