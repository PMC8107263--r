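#' Prediction probability (PK) from pair counts
#'
#' The prediction probability is the probability that the algorithm ranks
#' two randomly chosen reference-distinguished items in the same order as
#' the reference standard, with half credit for algorithm ties:
#' \deqn{P_K = \frac{C + \frac{1}{2} T_A}{C + D + T_A}}
#' Pairs tied in the reference (`TR`, `TB`) carry no ranking information
#' from the reference and do not enter. PK generalizes the trapezoidal
#' area under the ROC curve to continuous reference scores; a constant
#' submission scores exactly 0.5, and PK is invariant under strictly
#' increasing transforms of either score vector.
#'
#' @param counts a [`pair_counts`][count_pairs] object.
#' @return PK in \[0, 1\].
#' @examples
#' pk_from_counts(count_pairs(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4)))
#' @export
pk_from_counts <- function(counts) {
  counts <- as_pair_counts(counts)
  denom <- counts$C + counts$D + counts$TA
  if (denom == 0) {
    stop_undefined(paste0(
      "PK is undefined: no pair is distinguished by the reference ",
      "(C + D + TA = 0)"))
  }
  (counts$C + counts$TA / 2) / denom
}

#' Kendall's tau-b from pair counts
#'
#' Tie-corrected rank correlation
#' \deqn{\tau_B = \frac{C - D}{\sqrt{(C + D + T_A)(C + D + T_R)}}}
#' With `TA` and `TR` counting pairs tied in only one of the two vectors,
#' this is algebraically the standard tau-b. Unlike PK, tau-b rewards a
#' shrinking discordant count more than it penalizes algorithm ties, which
#' makes it gameable by deliberately binning continuous outputs; see
#' [run_gaming_experiment()].
#'
#' @inheritParams pk_from_counts
#' @return tau-b in \[-1, 1\].
#' @examples
#' tau_b_from_counts(count_pairs(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4)))
#' @export
tau_b_from_counts <- function(counts) {
  counts <- as_pair_counts(counts)
  d1 <- counts$C + counts$D + counts$TA
  d2 <- counts$C + counts$D + counts$TR
  if (d1 == 0 || d2 == 0) {
    stop_undefined("tau-b is undefined: a score vector distinguishes no pairs")
  }
  (counts$C - counts$D) / sqrt(d1 * d2)
}

#' Prediction probability of an algorithm against a reference
#'
#' Convenience composition of [count_pairs()] and [pk_from_counts()].
#'
#' @inheritParams count_pairs
#' @return PK in \[0, 1\].
#' @examples
#' prediction_probability(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4))
#' @export
prediction_probability <- function(ref_scores, alg_scores) {
  pk_from_counts(count_pairs(ref_scores, alg_scores))
}

#' Kendall's tau-b of an algorithm against a reference
#'
#' Convenience composition of [count_pairs()] and [tau_b_from_counts()].
#'
#' @inheritParams count_pairs
#' @return tau-b in \[-1, 1\].
#' @export
kendall_tau_b <- function(ref_scores, alg_scores) {
  tau_b_from_counts(count_pairs(ref_scores, alg_scores))
}

#' Trapezoidal (Mann-Whitney) AUC for a binary reference
#'
#' Rank-based area under the ROC curve with half credit for tied scores,
#' computed directly from mid-ranks rather than from pair counts. For a
#' binary reference this equals [prediction_probability()] exactly, which
#' is the sense in which PK generalizes the trapezoidal AUC.
#'
#' @param binary_ref vector of 0/1 class labels.
#' @param alg_scores numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @examples
#' trapezoidal_auc(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4))
#' @export
trapezoidal_auc <- function(binary_ref, alg_scores) {
  if (length(binary_ref) != length(alg_scores)) {
    stop_validation("length mismatch between labels and scores",
                    "pkeval_length_error")
  }
  if (!all(binary_ref %in% c(0, 1))) {
    stop_validation("binary_ref must contain only 0 and 1",
                    "pkeval_type_error")
  }
  if (!all(is.finite(alg_scores))) {
    stop_validation("scores must be finite", "pkeval_nonfinite_error")
  }
  n1 <- sum(binary_ref == 1)
  n0 <- sum(binary_ref == 0)
  if (n1 == 0 || n0 == 0) {
    stop_undefined("AUC is undefined: both classes must be present")
  }
  r <- rank(alg_scores, ties.method = "average")
  (sum(r[binary_ref == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average a metric over raters
#'
#' The challenge convention for multi-rater reference standards: the metric
#' is computed against each rater separately and the per-rater values are
#' averaged arithmetically into the summary score.
#'
#' @param per_rater_values numeric vector (or list) of per-rater metric values.
#' @return arithmetic mean.
#' @examples
#' average_metric_over_raters(c(path1 = 0.95, path2 = 0.91))
#' @export
average_metric_over_raters <- function(per_rater_values) {
  v <- unlist(per_rater_values, use.names = FALSE)
  if (length(v) == 0) {
    stop_validation("cannot average an empty set of per-rater values",
                    "pkeval_size_error")
  }
  if (!is.numeric(v) || !all(is.finite(v))) {
    stop_validation("per-rater values must be finite numbers",
                    "pkeval_nonfinite_error")
  }
  mean(v)
}
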