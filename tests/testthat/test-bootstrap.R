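make_gen <- function(n_patients, seed = 1, sd = 0.12) {
  generate_reference(
    synthetic_config(n_patients = n_patients, slides_per_patient = 1,
                     patches_per_slide = 12, rater_noise_sd = sd),
    seed = seed)
}

test_that("cluster bootstrap is bit-reproducible under a fixed seed", {
  gen <- make_gen(12)
  sub <- rater_as_submission(gen$reference, "path2")
  r1 <- cluster_bootstrap(metric_avg_pk, gen$reference, sub,
                          n_boot = 50, seed = 77)
  r2 <- cluster_bootstrap(metric_avg_pk, gen$reference, sub,
                          n_boot = 50, seed = 77)
  expect_identical(r1, r2)
  r3 <- cluster_bootstrap(metric_avg_pk, gen$reference, sub,
                          n_boot = 50, seed = 78)
  expect_false(identical(r1$replicates, r3$replicates))
})

test_that("a single cluster gives a zero-width CI at the point estimate", {
  ref <- reference_set(sprintf("p%d", 1:5), rep("s1", 5), rep("onlycase", 5),
                       cbind(path1 = c(0, 0.2, 0.5, 0.8, 1),
                             path2 = c(0, 0.3, 0.5, 0.7, 1)))
  sub <- rater_as_submission(ref, "path1")
  r <- cluster_bootstrap(metric_avg_pk, ref, sub, n_boot = 25, seed = 1)
  expect_identical(r$ci_low, r$value)
  expect_identical(r$ci_high, r$value)
})

test_that("CI brackets the point estimate and narrows with more patients", {
  widths <- sapply(c(20, 80), function(np) {
    gen <- make_gen(np, seed = 5)
    sub <- rater_as_submission(gen$reference, "path2")
    r <- cluster_bootstrap(metric_avg_pk, gen$reference, sub,
                           n_boot = 300, seed = 5)
    expect_lte(r$ci_low, r$value)
    expect_gte(r$ci_high, r$value)
    # percentile bracketing of the replicate distribution
    expect_equal(c(r$ci_low, r$ci_high),
                 unname(stats::quantile(r$replicates[!is.na(r$replicates)],
                                        c(0.025, 0.975))))
    r$ci_high - r$ci_low
  })
  expect_lt(widths[2], widths[1])
})

test_that("undefined replicates are dropped, counted, and warned about", {
  # one of three patients carries all the reference variation: resamples
  # without it leave the reference constant and PK undefined
  ref <- reference_set(sprintf("p%d", 1:6), rep("s1", 6),
                       c("A", "A", "B", "B", "C", "C"),
                       cbind(path1 = c(0.5, 0.5, 0.5, 0.5, 0.1, 0.9),
                             path2 = c(0.5, 0.5, 0.5, 0.5, 0.2, 0.8)))
  sub <- rater_as_submission(ref, "path2")
  expect_warning(
    r <- cluster_bootstrap(metric_avg_pk, ref, sub, n_boot = 60, seed = 2),
    "dropped")
  expect_gt(r$n_dropped, 0)
  expect_lte(r$n_dropped, r$n_boot)
  expect_equal(sum(is.na(r$replicates)), r$n_dropped)
})

test_that("identical submissions give a null paired difference", {
  gen <- make_gen(10)
  sub <- rater_as_submission(gen$reference, "path2")
  d <- paired_difference(metric_avg_pk, gen$reference, sub, sub,
                         n_boot = 40, seed = 3)
  expect_identical(d$delta, 0)
  expect_identical(c(d$ci_low, d$ci_high), c(0, 0))
  expect_false(d$significant)
})

test_that("swapping the compared algorithms mirrors the difference", {
  gen <- make_gen(15, seed = 9)
  a <- generate_algorithm(gen, algorithm_profile("a", noise_sd = 0.05),
                          seed = 11)
  b <- generate_algorithm(gen, algorithm_profile("b", noise_sd = 0.2),
                          seed = 12)
  ab <- paired_difference(metric_avg_pk, gen$reference, a, b,
                          n_boot = 200, seed = 4)
  ba <- paired_difference(metric_avg_pk, gen$reference, b, a,
                          n_boot = 200, seed = 4)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$ci_low, -ba$ci_high)
  expect_equal(ab$ci_high, -ba$ci_low)
  expect_identical(ab$significant, ba$significant)
})

test_that("a clearly better algorithm is declared significantly better", {
  hits <- sapply(1:10, function(s) {
    gen <- make_gen(50, seed = s)
    a <- generate_algorithm(gen, algorithm_profile("a", noise_sd = 0.03),
                            seed = s + 100)
    b <- generate_algorithm(gen, algorithm_profile("b", noise_sd = 0.25),
                            seed = s + 200)
    d <- paired_difference(metric_avg_pk, gen$reference, a, b,
                           n_boot = 200, seed = s)
    d$significant && d$delta > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("mismatched patch sets are rejected", {
  gen <- make_gen(5)
  a <- rater_as_submission(gen$reference, "path2")
  b <- submission("b", "b", a$scores[-1])
  expect_error(paired_difference(metric_avg_pk, gen$reference, a, b,
                                 n_boot = 10, seed = 1),
               class = "pkeval_coverage_error")
})
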