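test_that("scoring a rater's own scores gives per-rater PK of 1", {
  gen <- generate_reference(synthetic_config(n_patients = 8), seed = 2)
  ref <- gen$reference
  sub <- rater_as_submission(ref, "path1", team = "clone")
  e <- score_submission(sub, ref, n_boot = 0)
  expect_identical(unname(e$avg_pk$per_rater[["path1"]]), 1)
  inter <- prediction_probability(ref$scores[, "path2"],
                                  ref$scores[, "path1"])
  expect_equal(e$avg_pk$value, (1 + inter) / 2)
  expect_identical(unname(e$avg_icc$per_rater[["path1"]]), 1)
})

test_that("a constant submission scores average PK 0.5 with any raters", {
  ref <- tiny_reference()
  sub <- submission("flat", "flat",
                    stats::setNames(rep(0.42, 6), ref$patches$patch_id))
  e <- score_submission(sub, ref, n_boot = 0)
  expect_identical(e$avg_pk$value, 0.5)
})

test_that("monotone miscalibration keeps PK but costs ICC", {
  gen <- generate_reference(synthetic_config(n_patients = 8), seed = 3)
  ref <- gen$reference
  honest <- rater_as_submission(ref, "path1", team = "honest")
  warped <- submission("warped", "warped", honest$scores^2)
  eh <- score_submission(honest, ref, n_boot = 0)
  ew <- score_submission(warped, ref, n_boot = 0)
  expect_identical(ew$avg_pk$value, eh$avg_pk$value)
  expect_lt(ew$avg_icc$value, eh$avg_icc$value)
})

test_that("competition ranking shares ranks and skips after ties", {
  mk <- function(id, pk) {
    e <- list(team = id, entry_id = id,
              avg_pk = list(value = pk, ci_low = NA_real_,
                            ci_high = NA_real_,
                            per_rater = c(path1 = pk, path2 = pk)),
              avg_icc = list(value = pk, ci_low = NA_real_,
                             ci_high = NA_real_,
                             per_rater = c(path1 = pk, path2 = pk)))
    class(e) <- "scored_entry"
    e
  }
  board <- build_leaderboard(list(mk("w", 0.9), mk("x", 0.8),
                                  mk("y", 0.8), mk("z", 0.7)))
  expect_identical(board$rank, c(1L, 2L, 2L, 4L))
  single <- build_leaderboard(list(mk("only", 0.5)))
  expect_identical(single$rank, 1L)
  # permuting the input order leaves the board unchanged
  board2 <- build_leaderboard(list(mk("z", 0.7), mk("y", 0.8),
                                   mk("x", 0.8), mk("w", 0.9)))
  expect_identical(as.data.frame(board), as.data.frame(board2))
})

test_that("scoring is invariant to the patch order of the submission", {
  gen <- generate_reference(synthetic_config(n_patients = 6), seed = 4)
  ref <- gen$reference
  sub <- generate_algorithm(gen, algorithm_profile("a", 0.1), seed = 5)
  shuffled <- submission(sub$team, sub$entry_id,
                         sub$scores[sample(length(sub$scores))])
  e1 <- score_submission(sub, ref, n_boot = 30, seed = 6)
  e2 <- score_submission(shuffled, ref, n_boot = 30, seed = 6)
  expect_equal(e1$avg_pk, e2$avg_pk)
  expect_equal(e1$avg_icc, e2$avg_icc)
})

test_that("the significance frontier finds the first separable entry", {
  cfg <- synthetic_config(n_patients = 20, slides_per_patient = 1,
                          patches_per_slide = 20)
  gen <- generate_reference(cfg, seed = 7)
  subs <- list(
    rater_as_submission(gen$reference, "path1", team = "clone"),
    generate_algorithm(gen, algorithm_profile("noisy1", 0.3), seed = 8),
    generate_algorithm(gen, algorithm_profile("noisy2", 0.35), seed = 9))
  subs[[1]]$entry_id <- "clone"
  entries <- lapply(subs, score_submission, ref = gen$reference, n_boot = 0)
  board <- build_leaderboard(entries)
  expect_identical(board$entry_id[1], "clone")
  fr <- significance_frontier(board, gen$reference, subs,
                              n_boot = 200, seed = 10)
  expect_identical(unname(fr[["clone"]]), board$entry_id[2])
  # frontier positions never move above the next rank
  pos <- match(fr, board$entry_id)
  expect_true(all(is.na(pos) | pos > match(names(fr), board$entry_id)))
})

test_that("identical submissions produce no frontier", {
  gen <- generate_reference(synthetic_config(n_patients = 6), seed = 11)
  sub <- generate_algorithm(gen, algorithm_profile("a", 0.1), seed = 12)
  twin <- submission("b", "b", sub$scores)
  entries <- lapply(list(sub, twin), score_submission,
                    ref = gen$reference, n_boot = 0)
  board <- build_leaderboard(entries)
  expect_identical(board$rank, c(1L, 1L))
  fr <- significance_frontier(board, gen$reference, list(sub, twin),
                              n_boot = 50, seed = 13)
  expect_true(all(is.na(fr)))
})

test_that("leaderboard export round-trips through CSV and JSON", {
  gen <- generate_reference(synthetic_config(n_patients = 6), seed = 14)
  subs <- list(generate_algorithm(gen, algorithm_profile("a", 0.05), seed = 1),
               generate_algorithm(gen, algorithm_profile("b", 0.2), seed = 2))
  entries <- lapply(subs, score_submission, ref = gen$reference,
                    n_boot = 20, seed = 3)
  board <- build_leaderboard(entries)
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_leaderboard(board, fcsv, "csv")
  back <- utils::read.csv(fcsv)
  expect_identical(back$entry_id, board$entry_id)
  expect_equal(back$avg_pk, board$avg_pk)
  fjson <- withr::local_tempfile(fileext = ".json")
  write_leaderboard(board, fjson, "json")
  j <- jsonlite::read_json(fjson)
  expect_length(j$leaderboard, 2)
  expect_equal(j$leaderboard[[1]]$avg_pk$value, board$avg_pk[1])
  expect_identical(j$leaderboard[[1]]$avg_pk$n_boot, 20L)
})
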