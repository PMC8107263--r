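# Independent oracles. These deliberately avoid the package's own code
# paths: pair classes come from exhaustive enumeration of every unordered
# pair, and the ICC oracle reads its mean squares out of stats::aov.

brute_force_pairs <- function(x, y) {
  n <- length(x)
  iu <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dx <- x[iu[, 1]] - x[iu[, 2]]
  dy <- y[iu[, 1]] - y[iu[, 2]]
  list(C = sum(dx != 0 & dy != 0 & sign(dx) == sign(dy)),
       D = sum(dx != 0 & dy != 0 & sign(dx) != sign(dy)),
       TA = sum(dx != 0 & dy == 0),
       TR = sum(dx == 0 & dy != 0),
       TB = sum(dx == 0 & dy == 0))
}

expect_counts_equal <- function(counts, oracle) {
  expect_identical(
    c(C = counts$C, D = counts$D, TA = counts$TA, TR = counts$TR,
      TB = counts$TB),
    c(C = as.numeric(oracle$C), D = as.numeric(oracle$D),
      TA = as.numeric(oracle$TA), TR = as.numeric(oracle$TR),
      TB = as.numeric(oracle$TB)))
}

# textbook ICC(2,1) with mean squares taken from stats::aov
icc_aov_oracle <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  ms <- stats::setNames(tab[["Mean Sq"]], trimws(rownames(tab)))
  n <- nrow(m); k <- ncol(m)
  (ms[["subj"]] - ms[["Residuals"]]) /
    (ms[["subj"]] + (k - 1) * ms[["Residuals"]] +
       k * (ms[["rater"]] - ms[["Residuals"]]) / n)
}

# random score vector with a controllable amount of exact ties
random_scores <- function(n, tied = TRUE) {
  if (tied && stats::runif(1) < 0.7) {
    sample(seq(0, 1, by = sample(c(0.05, 0.1, 0.25), 1)), n, replace = TRUE)
  } else {
    stats::runif(n)
  }
}
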