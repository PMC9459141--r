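# Confidence-gated cascade fusing two classifier probabilities with a
# radiologist's binary verdict. Each model's confidence is its distance
# from maximal uncertainty, S = |0.5 - P| in [0, 0.5]; the fused score is
# the nested convex combination
#
#   S_fused = 2*S_svm * P_svm + (1 - 2*S_svm) * (2*S_rf * P_rf +
#             (1 - 2*S_rf) * V_reader)
#
# so a confident SVM dominates, an uncertain SVM defers to the RF, and two
# maximally uncertain models hand the case to the reader.

#' Confidence-gated fusion of classifier probabilities and a reader verdict
#'
#' Computes, per case, the confidence scores `s_svm = |0.5 - p_svm|` and
#' `s_rf = |0.5 - p_rf|` and the fused malignancy score
#' `s_mlad = 2*s_svm*p_svm + (1 - 2*s_svm) * (2*s_rf*p_rf +
#' (1 - 2*s_rf)*v_r)`. The score is a nested convex combination, so it
#' always lies in `[0, 1]`: it equals `p_svm` whenever the SVM is fully
#' confident (`p_svm` 0 or 1) and equals the reader verdict when both
#' models sit at 0.5. Note the fused score is deliberately not monotone in
#' `p_rf`: the RF contribution `2*|0.5 - p_rf|*p_rf` peaks inside
#' (0, 0.5), a direct consequence of confidence gating.
#'
#' Inputs are validated, not clamped; calibration of the upstream
#' probabilities is the caller's responsibility.
#'
#' @param p_svm,p_rf malignancy probabilities in `[0, 1]`.
#' @param v_r reader verdicts in `{0, 1}`.
#' @param threshold calling threshold on the fused score (default 0.5);
#'   ties go to malignant.
#' @return A tibble with columns `p_svm`, `p_rf`, `v_r`, `s_svm`, `s_rf`,
#'   `s_mlad`, `call`.
#' @export
#'
#' @examples
#' fuse_cohort(0.7, 0.3, 1)$s_mlad  # 0.712
fuse_cohort <- function(p_svm, p_rf, v_r, threshold = 0.5) {
  if (length(p_svm) != length(p_rf) || length(p_svm) != length(v_r)) {
    abort("`p_svm`, `p_rf` and `v_r` must have equal lengths.")
  }
  check_prob(p_svm, "p_svm")
  check_prob(p_rf, "p_rf")
  v_r <- check_binary(v_r, "v_r")
  s_svm <- abs(0.5 - p_svm)
  s_rf <- abs(0.5 - p_rf)
  inner <- 2 * s_rf * p_rf + (1 - 2 * s_rf) * v_r
  s_mlad <- 2 * s_svm * p_svm + (1 - 2 * s_svm) * inner
  tibble(p_svm = p_svm, p_rf = p_rf, v_r = v_r,
         s_svm = s_svm, s_rf = s_rf, s_mlad = s_mlad,
         call = as.integer(s_mlad >= threshold))
}

#' Fused score for a single case
#'
#' @inheritParams fuse_cohort
#' @return Single numeric fused score in `[0, 1]`.
#' @export
mlad_score <- function(p_svm, p_rf, v_r) {
  stopifnot(length(p_svm) == 1L, length(p_rf) == 1L, length(v_r) == 1L)
  fuse_cohort(p_svm, p_rf, v_r)$s_mlad
}

#' Binary call from a fused score
#'
#' `call = 1` iff the fused score is greater than or equal to the
#' threshold: a score exactly at the threshold is called malignant.
#'
#' @param s_mlad fused scores in `[0, 1]`.
#' @param threshold calling threshold (default 0.5).
#' @return Integer 0/1 calls.
#' @export
mlad_classify <- function(s_mlad, threshold = 0.5) {
  check_prob(s_mlad, "s_mlad")
  as.integer(s_mlad >= threshold)
}
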