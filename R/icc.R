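## Calibration-sensitive agreement: ICC(2,1), two-way random effects,
## absolute agreement, single rater (Shrout & Fleiss convention).

check_rating_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) {
    stop_validation("rating matrix must be numeric", "pkeval_type_error")
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_validation(
      "rating matrix needs at least 2 subjects (rows) and 2 raters (columns)",
      "pkeval_size_error")
  }
  if (!all(is.finite(m))) {
    stop_validation(
      "rating matrix must be complete and finite; missing cells are rejected, not imputed",
      "pkeval_nonfinite_error")
  }
  m
}

#' Two-way ANOVA mean squares for a subjects-by-raters rating matrix
#'
#' Decomposes a complete n-subjects-by-k-raters score grid (one observation
#' per cell) into between-subject, between-rater, and residual mean squares,
#' the building blocks of the intraclass correlation.
#'
#' @param m numeric matrix, subjects in rows, raters in columns; complete,
#'   at least 2 rows and 2 columns.
#' @return list with `ms_rows`, `ms_cols`, `ms_err`, `n` (subjects),
#'   `k` (raters).
#' @examples
#' anova_mean_squares(cbind(c(1, 2, 3), c(2, 3, 4)))
#' @export
anova_mean_squares <- function(m) {
  m <- check_rating_matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  list(ms_rows = ss_rows / (n - 1),
       ms_cols = ss_cols / (k - 1),
       ms_err = max(0, ss_err) / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlation ICC(2,1): two-way random, absolute agreement
#'
#' Single-rater intraclass correlation under the two-way random-effects
#' model with absolute agreement:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the between-subject,
#' between-rater, and residual mean squares. Unlike rank-based concordance,
#' ICC(2,1) penalizes calibration differences: adding a constant offset to
#' one rater lowers it while leaving PK untouched. Negative values are
#' returned as computed, not clipped.
#'
#' @inheritParams anova_mean_squares
#' @return ICC(2,1), at most 1; equals 1 only for identical columns.
#' @examples
#' icc_2_1(cbind(c(1, 2, 3), c(2, 3, 4)))
#' @export
icc_2_1 <- function(m) {
  ms <- anova_mean_squares(m)
  denom <- ms$ms_rows + (ms$k - 1) * ms$ms_err +
    ms$k * (ms$ms_cols - ms$ms_err) / ms$n
  if (abs(denom) < .Machine$double.eps * 100) {
    stop_undefined(
      "ICC(2,1) is undefined: zero denominator (no variance to apportion)")
  }
  (ms$ms_rows - ms$ms_err) / denom
}
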