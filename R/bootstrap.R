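## Patient-clustered percentile bootstrap.
##
## Replicate r draws patients (clusters) with replacement; all patches of a
## drawn patient enter the replicate together (twice if drawn twice), so the
## within-patient correlation of patch scores is respected. Each replicate
## uses an RNG seed derived from (root seed, r), making the replicate vector
## independent of evaluation order.

derive_seed <- function(root, r) {
  m <- 2147483647  # 2^31 - 1; products below stay exact in doubles
  s <- (as.double(root) %% m) * 48271 + as.double(r)
  s <- (s %% m) * 48271 + 1
  as.integer(s %% m)
}

cluster_indices <- function(ref) {
  split(seq_len(n_patches(ref)), ref$patches$case_id)
}

#' Built-in metric evaluators
#'
#' Metric evaluators take a [reference_set()] (possibly a bootstrap
#' replicate, where patches repeat) and a numeric vector of algorithm scores
#' aligned to its patches, and return a scalar. `metric_avg_pk` is the
#' challenge's primary endpoint: prediction probability against each rater,
#' averaged over raters. `metric_avg_icc` is the calibration-sensitive
#' secondary endpoint: ICC(2,1) of the two-column (algorithm, rater) matrix,
#' averaged over raters.
#'
#' @param ref a [reference_set()].
#' @param alg_scores numeric vector aligned to `ref$patches`.
#' @return scalar metric value.
#' @export
metric_avg_pk <- function(ref, alg_scores) {
  vals <- vapply(ref$rater_ids, function(r) {
    prediction_probability(ref$scores[, r], alg_scores)
  }, numeric(1))
  average_metric_over_raters(vals)
}

#' @rdname metric_avg_pk
#' @export
metric_avg_icc <- function(ref, alg_scores) {
  vals <- vapply(ref$rater_ids, function(r) {
    icc_2_1(cbind(alg = alg_scores, rater = ref$scores[, r]))
  }, numeric(1))
  average_metric_over_raters(vals)
}

#' Patient-clustered bootstrap confidence interval for a metric
#'
#' Resamples patients (the `case_id` clusters of the reference set) with
#' replacement, re-evaluates the metric on each replicate, and reports the
#' percentile confidence interval at the requested coverage. The point
#' estimate is always computed on the full, unresampled data. Replicates on
#' which the metric is undefined (e.g. a resample whose reference scores are
#' constant) are dropped and counted in `n_dropped`, with a warning.
#'
#' @param metric evaluator `function(ref, alg_scores)` returning a scalar;
#'   see [metric_avg_pk()].
#' @param ref a [reference_set()]; every patch must carry a `case_id`.
#' @param sub a [submission()] covering every reference patch.
#' @param n_boot number of bootstrap replicates (the challenge used 1000).
#' @param seed integer root seed; replicate `r` uses a stream derived from
#'   `(seed, r)`, so identical inputs and seed reproduce identical results.
#' @param level CI coverage, default 0.95 (percentile 2.5/97.5).
#' @return object of class `metric_result`: `value`, `ci_low`, `ci_high`,
#'   `level`, `n_boot`, `n_dropped`, `seed`, `per_rater` (optional map),
#'   and the replicate values in `replicates`.
#' @export
cluster_bootstrap <- function(metric, ref, sub, n_boot = 1000, seed = 1,
                              level = 0.95) {
  if (n_boot < 1) {
    stop_validation("n_boot must be at least 1", "pkeval_size_error")
  }
  alg <- aligned_scores(sub, ref)
  value <- metric(ref, alg)
  cl_idx <- cluster_indices(ref)
  m <- length(cl_idx)
  reps <- vapply(seq_len(n_boot), function(r) {
    set.seed(derive_seed(seed, r))
    draw <- sample.int(m, m, replace = TRUE)
    idx <- unlist(cl_idx[draw], use.names = FALSE)
    tryCatch(metric(ref_subset(ref, idx), alg[idx]),
             pkeval_undefined_metric = function(e) NA_real_)
  }, numeric(1))
  kept <- reps[!is.na(reps)]
  n_dropped <- n_boot - length(kept)
  if (length(kept) == 0) {
    stop_undefined("metric undefined on every bootstrap replicate")
  }
  if (n_dropped > 0) {
    warning(sprintf("%d of %d bootstrap replicates dropped (metric undefined)",
                    n_dropped, n_boot))
  }
  ci <- quantile(kept, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(
    list(value = value, ci_low = ci[1], ci_high = ci[2], level = level,
         n_boot = n_boot, n_dropped = n_dropped, seed = seed,
         per_rater = NULL, replicates = reps),
    class = "metric_result")
}

#' @export
print.metric_result <- function(x, digits = 3, ...) {
  cat(sprintf("%.*f [%s, %s] (%d%% percentile CI, %d bootstrap replicates%s)\n",
              digits, x$value,
              if (is.na(x$ci_low)) "NA" else sprintf("%.*f", digits, x$ci_low),
              if (is.na(x$ci_high)) "NA" else sprintf("%.*f", digits, x$ci_high),
              round(100 * x$level), x$n_boot,
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  if (!is.null(x$per_rater)) {
    cat("  per rater:",
        paste(sprintf("%s=%.*f", names(x$per_rater), digits, x$per_rater),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired bootstrap comparison of two algorithms
#'
#' Tests whether algorithm A's metric differs from algorithm B's by applying
#' the *same* resampled patient set to both submissions in every replicate
#' and taking the percentile CI of the replicate-wise difference A - B. The
#' difference is significant at level `alpha` exactly when that CI excludes
#' zero.
#'
#' @inheritParams cluster_bootstrap
#' @param subA,subB two [submission()]s covering the same patch set.
#' @param alpha significance level (CI coverage is `1 - alpha`).
#' @return object of class `difference_result`: `delta` (point difference on
#'   the full data), `ci_low`, `ci_high`, `significant`, `alpha`, `n_boot`,
#'   `n_dropped`, `seed`, `replicates`.
#' @export
paired_difference <- function(metric, ref, subA, subB, n_boot = 1000,
                              seed = 1, alpha = 0.05) {
  if (n_boot < 1) {
    stop_validation("n_boot must be at least 1", "pkeval_size_error")
  }
  if (!setequal(names(subA$scores), names(subB$scores))) {
    stop_validation("submissions A and B must cover the same patch set",
                    "pkeval_coverage_error")
  }
  a <- aligned_scores(subA, ref)
  b <- aligned_scores(subB, ref)
  delta <- metric(ref, a) - metric(ref, b)
  cl_idx <- cluster_indices(ref)
  m <- length(cl_idx)
  reps <- vapply(seq_len(n_boot), function(r) {
    set.seed(derive_seed(seed, r))
    draw <- sample.int(m, m, replace = TRUE)
    idx <- unlist(cl_idx[draw], use.names = FALSE)
    ref_r <- ref_subset(ref, idx)
    tryCatch(metric(ref_r, a[idx]) - metric(ref_r, b[idx]),
             pkeval_undefined_metric = function(e) NA_real_)
  }, numeric(1))
  kept <- reps[!is.na(reps)]
  n_dropped <- n_boot - length(kept)
  if (length(kept) == 0) {
    stop_undefined("metric undefined on every bootstrap replicate")
  }
  if (n_dropped > 0) {
    warning(sprintf("%d of %d bootstrap replicates dropped (metric undefined)",
                    n_dropped, n_boot))
  }
  ci <- quantile(kept, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(delta = delta, ci_low = ci[1], ci_high = ci[2],
         significant = ci[1] > 0 || ci[2] < 0, alpha = alpha,
         n_boot = n_boot, n_dropped = n_dropped, seed = seed,
         replicates = reps),
    class = "difference_result")
}

#' @export
print.difference_result <- function(x, digits = 4, ...) {
  cat(sprintf("delta = %.*f [%.*f, %.*f], %ssignificant at alpha = %g\n",
              digits, x$delta, digits, x$ci_low, digits, x$ci_high,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
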