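#' Patch-level mean squared error across a field of algorithms
#'
#' Post-hoc error analysis identifying which patches the submitted
#' algorithms, as a group, scored well or poorly. For each patch and each
#' rater, the squared difference between the rater's score and each
#' algorithm's prediction is averaged over algorithms; the patch MSE is then
#' the average of those per-rater values across raters. High-MSE patches are
#' the ones the whole algorithm field struggled with.
#'
#' When every rater gives the same score s to a patch, the patch MSE
#' decomposes exactly into (mean algorithm score - s)^2 plus the population
#' variance of the algorithm scores.
#'
#' @param submissions non-empty list of [submission()]s, all covering the
#'   reference patch set.
#' @param ref a [reference_set()].
#' @return data.frame of class `patch_mse`, sorted by `mse` descending:
#'   `patch_id`, `mse`, `avg_score` (mean algorithm score), `sd_score`
#'   (sample SD of algorithm scores), plus the per-rater reference scores.
#' @export
patch_mse <- function(submissions, ref) {
  if (length(submissions) == 0) {
    stop_validation("need at least one submission", "pkeval_size_error")
  }
  alg <- vapply(submissions, function(s) aligned_scores(s, ref),
                numeric(n_patches(ref)))          # patches x algorithms
  alg <- matrix(alg, nrow = n_patches(ref))
  per_rater_mse <- vapply(ref$rater_ids, function(r) {
    rowMeans((alg - ref$scores[, r])^2)
  }, numeric(n_patches(ref)))
  per_rater_mse <- matrix(per_rater_mse, nrow = n_patches(ref))
  df <- data.frame(
    patch_id = ref$patches$patch_id,
    mse = rowMeans(per_rater_mse),
    avg_score = rowMeans(alg),
    sd_score = apply(alg, 1, sd),
    stringsAsFactors = FALSE)
  for (r in ref$rater_ids) df[[r]] <- ref$scores[, r]
  df <- df[order(-df$mse, df$patch_id), ]
  rownames(df) <- NULL
  class(df) <- c("patch_mse", "data.frame")
  df
}
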