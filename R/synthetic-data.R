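# Synthetic-data generators. Every generator is a pure function of its
# configuration and seed, so downstream stages are testable against known
# ground truth without any external data.

#' Cohort simulation configuration
#'
#' Describes a two-class radiomics cohort: `n_benign` + `n_malignant`
#' patients by `p_features` features, of which `k_informative` are mean
#' shifted by `effect_size` within-class standard deviations in the
#' malignant class. Features are organized in correlated blocks (block size
#' 10) with within-block correlation `block_rho` via a shared-factor model,
#' so marginal within-class variance is 1 and `effect_size` is in SD units.
#'
#' @param n_benign,n_malignant class sizes (>= 1).
#' @param p_features number of features.
#' @param k_informative number of informative features
#'   (`<= p_features`).
#' @param effect_size malignant-class mean shift in within-class SD units.
#' @param block_rho within-block correlation in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_benign = 113, n_malignant = 118,
                          p_features = 100, k_informative = 10,
                          effect_size = 1, block_rho = 0.3, seed = 1L) {
  check_count(n_benign, "n_benign")
  check_count(n_malignant, "n_malignant")
  check_count(p_features, "p_features")
  check_count(k_informative, "k_informative", min = 0L)
  if (k_informative > p_features) {
    abort("`k_informative` must not exceed `p_features`.")
  }
  if (block_rho < 0 || block_rho >= 1) abort("`block_rho` must be in [0, 1).")
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 p_features = as.integer(p_features),
                 k_informative = as.integer(k_informative),
                 effect_size = effect_size, block_rho = block_rho,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Reader performance profile
#'
#' Sensitivity/specificity pair for a simulated radiologist verdict. The
#' default tiers mirror a typical MRI reading study: juniors (< 5 years)
#' with sensitivity 0.63 and specificity 0.67, seniors (> 10 years) with
#' sensitivity 0.63 and specificity 0.87.
#'
#' @param sensitivity,specificity probabilities in `[0, 1]`.
#' @param tier `"junior"` or `"senior"`.
#' @return A list of class `reader_profile`.
#' @export
reader_profile <- function(sensitivity = 0.63, specificity = 0.87,
                           tier = c("senior", "junior")) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 tier = match.arg(tier)),
            class = "reader_profile")
}

#' Rater-noise configuration for reproducibility simulation
#'
#' Two raters measure the same per-subject feature values with independent
#' measurement noise. The implied true intraclass correlation is
#' `sigma_subject^2 / (sigma_subject^2 + sigma_noise^2)`.
#'
#' @param sigma_subject SD of the shared per-subject effect (>= 0).
#' @param sigma_noise SD of the per-rater measurement noise (>= 0).
#' @param seed integer RNG seed.
#' @return A list of class `rater_noise_config` with an extra element
#'   `true_icc`.
#' @export
rater_noise_config <- function(sigma_subject = 1, sigma_noise = 0.3,
                               seed = 1L) {
  if (sigma_subject < 0 || sigma_noise < 0) abort("SDs must be >= 0.")
  tot <- sigma_subject^2 + sigma_noise^2
  structure(list(sigma_subject = sigma_subject, sigma_noise = sigma_noise,
                 seed = as.integer(seed),
                 true_icc = if (tot == 0) NA_real_ else sigma_subject^2 / tot),
            class = "rater_noise_config")
}

#' Generate a two-class feature table with known informative features
#'
#' Draws a `(n_benign + n_malignant) x p_features` Gaussian feature matrix
#' in correlated blocks, shifts a random subset of `k_informative` features
#' by `effect_size` SD in the malignant class, and attaches 0/1 pathology
#' labels. The index set of informative features is returned as the
#' `informative` attribute (feature names as the `informative_features`
#' attribute).
#'
#' @param config a [cohort_config()].
#' @param lognormal if `TRUE`, features are exponentiated, giving skewed
#'   (log-normal) marginals that exercise rank-based screening.
#' @return A tibble with feature columns `feat_0001 ...` and a `label`
#'   column (0 benign, 1 malignant), with attributes `informative`
#'   (integer indices) and `informative_features` (names).
#' @export
#'
#' @examples
#' tab <- gen_feature_table(cohort_config(n_benign = 5, n_malignant = 5,
#'                                        p_features = 8, k_informative = 2))
#' attr(tab, "informative")
gen_feature_table <- function(config, lognormal = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_benign + config$n_malignant
  p <- config$p_features
  block_size <- 10L
  block <- ((seq_len(p) - 1L) %/% block_size) + 1L
  n_blocks <- max(block)
  z <- matrix(rnorm(n * n_blocks), n, n_blocks)
  e <- matrix(rnorm(n * p), n, p)
  rho <- config$block_rho
  x <- sqrt(rho) * z[, block, drop = FALSE] + sqrt(1 - rho) * e
  labels <- c(rep(0L, config$n_benign), rep(1L, config$n_malignant))
  informative <- sort(sample.int(p, config$k_informative))
  if (length(informative)) {
    x[labels == 1L, informative] <- x[labels == 1L, informative] +
      config$effect_size
  }
  if (lognormal) x <- exp(x)
  feat_names <- sprintf("feat_%04d", seq_len(p))
  colnames(x) <- feat_names
  out <- as_tibble(x)
  out$label <- labels
  attr(out, "informative") <- informative
  attr(out, "informative_features") <- feat_names[informative]
  out
}

#' Generate paired rater measurements for reproducibility analysis
#'
#' Each of `n_subjects` subjects has, per feature, a true value drawn with
#' SD `sigma_subject`; the two raters observe it with independent noise of
#' SD `sigma_noise`. The per-feature intraclass correlation therefore has
#' ground truth `sigma_subject^2 / (sigma_subject^2 + sigma_noise^2)`.
#'
#' @param config a [rater_noise_config()].
#' @param n_subjects number of subjects (>= 3).
#' @param n_features number of features.
#' @return List with tibbles `rater_a` and `rater_b` (same subjects, same
#'   feature columns) and the implied `true_icc`.
#' @export
gen_rater_pairs <- function(config, n_subjects = 30, n_features = 20) {
  stopifnot(inherits(config, "rater_noise_config"))
  check_count(n_features, "n_features")
  if (n_subjects < 3) {
    abort("`n_subjects` must be >= 3 for a meaningful ICC estimate.")
  }
  set.seed(config$seed)
  truth <- matrix(rnorm(n_subjects * n_features, sd = config$sigma_subject),
                  n_subjects, n_features)
  noise_a <- matrix(rnorm(n_subjects * n_features, sd = config$sigma_noise),
                    n_subjects, n_features)
  noise_b <- matrix(rnorm(n_subjects * n_features, sd = config$sigma_noise),
                    n_subjects, n_features)
  feat_names <- sprintf("feat_%04d", seq_len(n_features))
  a <- truth + noise_a
  b <- truth + noise_b
  colnames(a) <- colnames(b) <- feat_names
  list(rater_a = as_tibble(a), rater_b = as_tibble(b),
       true_icc = config$true_icc)
}

#' Simulate radiologist verdicts at a stated sensitivity/specificity
#'
#' Verdicts are independent across cases: a malignant case is called 1 with
#' probability `sensitivity`, a benign case is called 0 with probability
#' `specificity`.
#'
#' @param labels 0/1 pathology labels.
#' @param profile a [reader_profile()].
#' @param seed integer RNG seed.
#' @return Integer 0/1 verdict vector aligned with `labels`.
#' @export
gen_reader_calls <- function(labels, profile = reader_profile(), seed = 1L) {
  labels <- check_binary(labels, "labels")
  stopifnot(inherits(profile, "reader_profile"))
  set.seed(seed)
  p_call1 <- ifelse(labels == 1L, profile$sensitivity, 1 - profile$specificity)
  as.integer(runif(length(labels)) < p_call1)
}

# separable periodic Gaussian smoothing, reusing the circulant filter
gaussian_smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (ax in 1:3) vol <- apply_filter_axis(vol, k, ax)
  vol
}

#' Generate textured ROI volumes with class-dependent heterogeneity
#'
#' Benign volumes are smooth spatially correlated Gaussian fields
#' (correlation length `smooth_sigma` voxels) rescaled into an 8-bit-like
#' grayscale range; malignant volumes add a high-frequency heterogeneous
#' component of SD `heterogeneity` gray levels (correlation length
#' `hetero_sigma`), so texture features separate the classes. Masks are
#' centered ellipsoids with semi-axes 0.38 of each extent.
#'
#' @param n_per_class volumes per class.
#' @param shape 3D extents, each >= 8.
#' @param smooth_sigma correlation length (voxels) of the base field.
#' @param heterogeneity SD (gray levels) of the malignant high-frequency
#'   component; 0 makes the classes indistinguishable.
#' @param hetero_sigma correlation length (voxels) of that component.
#' @param base_mean,base_sd grayscale mean and SD of the base field.
#' @param seed integer RNG seed.
#' @return A list with `volumes` (list of [roi_volume()]) and `labels`
#'   (0 benign / 1 malignant), in benign-then-malignant order.
#' @export
gen_roi_volumes <- function(n_per_class = 40, shape = c(20, 20, 12),
                            smooth_sigma = 3, heterogeneity = 40,
                            hetero_sigma = 0.5, base_mean = 128,
                            base_sd = 30, seed = 1L) {
  check_count(n_per_class, "n_per_class")
  if (length(shape) != 3L || any(shape < 8)) {
    abort("`shape` must be 3 extents, each >= 8.")
  }
  shape <- as.integer(shape)
  set.seed(seed)
  ax <- lapply(shape, function(n) seq_len(n) - (n + 1) / 2)
  semi <- 0.38 * shape
  r2 <- outer(outer((ax[[1]] / semi[1])^2, (ax[[2]] / semi[2])^2, "+"),
              (ax[[3]] / semi[3])^2, "+")
  mask <- r2 <= 1
  one_volume <- function(malignant) {
    base <- gaussian_smooth3d(array(rnorm(prod(shape)), shape), smooth_sigma)
    base <- (base - mean(base)) / sd(base) * base_sd + base_mean
    if (malignant && heterogeneity > 0) {
      het <- gaussian_smooth3d(array(rnorm(prod(shape)), shape), hetero_sigma)
      het <- het / sd(het) * heterogeneity
      base <- base + het
    }
    roi_volume(pmin(pmax(base, 0), 255), mask)
  }
  labels <- c(rep(0L, n_per_class), rep(1L, n_per_class))
  volumes <- lapply(labels, function(l) one_volume(l == 1L))
  list(volumes = volumes, labels = labels)
}
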