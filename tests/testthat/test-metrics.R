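test_that("PK matches the formula on worked examples and edge cases", {
  expect_equal(pk_from_counts(count_pairs(c(0.1, 0.2, 0.3, 0.4),
                                          c(0.1, 0.3, 0.2, 0.4))), 5 / 6)
  expect_equal(prediction_probability(c(0, 0, 1, 1),
                                      c(0.2, 0.3, 0.3, 0.4)), 0.875)
  # identical scores: every reference-distinguished pair concordant
  x <- c(0.1, 0.4, 0.4, 0.7, 0.9)
  expect_identical(prediction_probability(x, x), 1)
  # full reversal with no algorithm ties among distinguished pairs
  expect_identical(prediction_probability(x, -x), 0)
  # constant reference leaves PK undefined
  expect_error(prediction_probability(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               class = "pkeval_undefined_metric")
})

test_that("constant submissions always score PK exactly 0.5", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    ref <- random_scores(n)
    if (length(unique(ref)) < 2) ref[1] <- ref[1] + 0.5
    expect_identical(prediction_probability(ref, rep(0.37, n)), 0.5)
  }
})

test_that("PK and tau-b are invariant under strictly increasing transforms", {
  set.seed(6)
  transforms <- list(function(z) z^3, function(z) 2 * z - 5,
                     function(z) exp(z), function(z) atan(z))
  for (i in 1:25) {
    n <- sample(4:80, 1)
    x <- random_scores(n)
    y <- random_scores(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    f <- transforms[[sample(length(transforms), 1)]]
    g <- transforms[[sample(length(transforms), 1)]]
    expect_identical(prediction_probability(x, y),
                     prediction_probability(g(x), f(y)))
    expect_identical(kendall_tau_b(x, y), kendall_tau_b(g(x), f(y)))
  }
})

test_that("negating algorithm scores swaps C and D and reflects PK, tau-b", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:80, 1)
    x <- random_scores(n)
    y <- random_scores(n)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    a <- count_pairs(x, y)
    b <- count_pairs(x, -y)
    expect_identical(c(b$C, b$D, b$TA, b$TR, b$TB),
                     c(a$D, a$C, a$TA, a$TR, a$TB))
    expect_equal(pk_from_counts(b), 1 - pk_from_counts(a))
    expect_equal(tau_b_from_counts(b), -tau_b_from_counts(a))
  }
})

test_that("tau-b equals the hand formula and R's tie-corrected Kendall", {
  expect_equal(tau_b_from_counts(count_pairs(c(0.1, 0.2, 0.3, 0.4),
                                             c(0.1, 0.3, 0.2, 0.4))), 4 / 6)
  expect_equal(kendall_tau_b(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4)),
               3 / sqrt(4 * 5))
  # perfect agreement without ties
  expect_identical(kendall_tau_b(1:10, (1:10)^2), 1)
  set.seed(8)
  for (i in 1:40) {
    n <- sample(4:100, 1)
    x <- random_scores(n, tied = i %% 2 == 0)
    y <- random_scores(n, tied = i %% 2 == 0)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    cts <- count_pairs(x, y)
    hand <- (cts$C - cts$D) /
      sqrt((cts$C + cts$D + cts$TA) * (cts$C + cts$D + cts$TR))
    expect_equal(tau_b_from_counts(cts), hand, tolerance = 1e-12)
    expect_equal(tau_b_from_counts(cts),
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
})

test_that("PK on a binary reference is the trapezoidal AUC", {
  expect_equal(trapezoidal_auc(c(0, 0, 1, 1), c(0.2, 0.3, 0.3, 0.4)), 0.875)
  expect_identical(trapezoidal_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_identical(trapezoidal_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(trapezoidal_auc(c(0, 0, 0), c(1, 2, 3)),
               class = "pkeval_undefined_metric")
  set.seed(9)
  for (i in 1:30) {
    n <- sample(6:100, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- random_scores(n)
    auc <- trapezoidal_auc(lab, sc)
    expect_equal(prediction_probability(lab, sc), auc, tolerance = 1e-12)
    proc <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                           direction = "<")))
    expect_equal(auc, proc, tolerance = 1e-12)
  }
})

test_that("averaging over raters is the arithmetic mean and rejects junk", {
  expect_equal(average_metric_over_raters(c(0.95, 0.91)), 0.93)
  expect_identical(average_metric_over_raters(0.7), 0.7)
  expect_identical(average_metric_over_raters(c(1, 0)), 0.5)
  expect_error(average_metric_over_raters(numeric()),
               class = "pkeval_size_error")
  expect_error(average_metric_over_raters(c(0.9, NA)),
               class = "pkeval_nonfinite_error")
})
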