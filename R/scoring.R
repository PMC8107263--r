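#' Score one submission against a multi-rater reference
#'
#' Computes the challenge's two endpoints for a validated submission:
#' average PK (primary, rank-based) and average ICC(2,1) (secondary,
#' calibration-sensitive), each as a per-rater breakdown plus the
#' rater-averaged summary with a patient-clustered bootstrap CI. The
#' bootstrap re-averages over raters inside every replicate.
#'
#' @param sub a [submission()] covering every reference patch.
#' @param ref a [reference_set()].
#' @param n_boot bootstrap replicates for the CIs; `0` skips the bootstrap
#'   (point estimates only, `NA` CI bounds), useful when only ranks are
#'   needed.
#' @param seed root RNG seed for the bootstrap.
#' @param level CI coverage.
#' @return object of class `scored_entry`: `team`, `entry_id`, `avg_pk` and
#'   `avg_icc` ([cluster_bootstrap()] results carrying `per_rater` maps).
#' @export
score_submission <- function(sub, ref, n_boot = 1000, seed = 1,
                             level = 0.95) {
  alg <- aligned_scores(sub, ref)
  per_pk <- vapply(ref$rater_ids, function(r) {
    prediction_probability(ref$scores[, r], alg)
  }, numeric(1))
  per_icc <- vapply(ref$rater_ids, function(r) {
    icc_2_1(cbind(alg = alg, rater = ref$scores[, r]))
  }, numeric(1))
  if (n_boot >= 1) {
    avg_pk <- cluster_bootstrap(metric_avg_pk, ref, sub, n_boot = n_boot,
                                seed = seed, level = level)
    avg_icc <- cluster_bootstrap(metric_avg_icc, ref, sub, n_boot = n_boot,
                                 seed = seed, level = level)
  } else {
    point <- function(v) {
      structure(list(value = average_metric_over_raters(v), ci_low = NA_real_,
                     ci_high = NA_real_, level = level, n_boot = 0L,
                     n_dropped = 0L, seed = seed, per_rater = NULL,
                     replicates = numeric()),
                class = "metric_result")
    }
    avg_pk <- point(per_pk)
    avg_icc <- point(per_icc)
  }
  avg_pk$per_rater <- per_pk
  avg_icc$per_rater <- per_icc
  structure(list(team = sub$team, entry_id = sub$entry_id,
                 avg_pk = avg_pk, avg_icc = avg_icc),
            class = "scored_entry")
}

#' @export
print.scored_entry <- function(x, ...) {
  cat(sprintf("Entry %s/%s\n", x$team, x$entry_id))
  cat("  avg PK : "); print(x$avg_pk)
  cat("  avg ICC: "); print(x$avg_icc)
  invisible(x)
}

#' Build a leaderboard from scored entries
#'
#' Sorts entries by average PK descending and assigns competition ranks:
#' tied values share the smaller rank and the next rank is skipped
#' (values 0.9, 0.8, 0.8, 0.7 rank 1, 2, 2, 4). Ties are displayed in
#' deterministic secondary order by `entry_id`.
#'
#' @param entries list of [score_submission()] results.
#' @return object of class `leaderboard`: a data.frame with columns `rank`,
#'   `team`, `entry_id`, `avg_pk`, `pk_ci_low`, `pk_ci_high`, `avg_icc`,
#'   `icc_ci_low`, `icc_ci_high`, plus per-rater PK columns `pk_<rater>`;
#'   the scored entries ride along in `attr(, "entries")`.
#' @export
build_leaderboard <- function(entries) {
  if (length(entries) == 0) {
    stop_validation("need at least one scored entry", "pkeval_size_error")
  }
  pk <- vapply(entries, function(e) e$avg_pk$value, numeric(1))
  eid <- vapply(entries, function(e) e$entry_id, character(1))
  ord <- order(-pk, eid)
  entries <- entries[ord]
  pk <- pk[ord]
  rank <- integer(length(pk))
  for (i in seq_along(pk)) {
    rank[i] <- if (i > 1 && pk[i] == pk[i - 1]) rank[i - 1] else i
  }
  df <- data.frame(
    rank = rank,
    team = vapply(entries, function(e) e$team, character(1)),
    entry_id = vapply(entries, function(e) e$entry_id, character(1)),
    avg_pk = pk,
    pk_ci_low = vapply(entries, function(e) e$avg_pk$ci_low, numeric(1)),
    pk_ci_high = vapply(entries, function(e) e$avg_pk$ci_high, numeric(1)),
    avg_icc = vapply(entries, function(e) e$avg_icc$value, numeric(1)),
    icc_ci_low = vapply(entries, function(e) e$avg_icc$ci_low, numeric(1)),
    icc_ci_high = vapply(entries, function(e) e$avg_icc$ci_high, numeric(1)),
    stringsAsFactors = FALSE)
  raters <- names(entries[[1]]$avg_pk$per_rater)
  for (r in raters) {
    df[[paste0("pk_", r)]] <-
      vapply(entries, function(e) e$avg_pk$per_rater[[r]], numeric(1))
  }
  structure(df, entries = entries, class = c("leaderboard", "data.frame"))
}

#' @export
print.leaderboard <- function(x, digits = 3, ...) {
  cat("Leaderboard (sorted by average PK)\n")
  shown <- as.data.frame(x)
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = digits)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Significance frontier down a leaderboard
#'
#' For each queried entry, walks down the ranking and applies
#' [paired_difference()] (average PK, same resampled patients for both
#' algorithms) against each lower-ranked entry until a significant
#' difference is found. The recorded entry is the first lower-ranked
#' algorithm from which the queried one is statistically separated — the
#' horizontal "frontier" drawn on challenge ranking plots.
#'
#' @param leaderboard a [build_leaderboard()] result.
#' @param ref the [reference_set()] used for scoring.
#' @param submissions list of the raw [submission()]s, in any order; matched
#'   to leaderboard rows by `entry_id`.
#' @param entry_ids entries to query (default: all rows).
#' @param metric evaluator used for the comparison, default [metric_avg_pk()].
#' @param alpha significance level.
#' @param n_boot,seed bootstrap controls for each pairwise comparison.
#' @return named character vector: for each queried entry id, the entry id
#'   of its frontier, or `NA` if no lower-ranked entry differs significantly.
#' @export
significance_frontier <- function(leaderboard, ref, submissions,
                                  entry_ids = leaderboard$entry_id,
                                  metric = metric_avg_pk, alpha = 0.05,
                                  n_boot = 1000, seed = 1) {
  sub_by_id <- stats::setNames(
    submissions, vapply(submissions, function(s) s$entry_id, character(1)))
  out <- stats::setNames(rep(NA_character_, length(entry_ids)), entry_ids)
  board_ids <- leaderboard$entry_id
  for (eid in entry_ids) {
    pos <- match(eid, board_ids)
    if (is.na(pos)) {
      stop_validation(sprintf("entry '%s' is not on the leaderboard", eid),
                      "pkeval_coverage_error")
    }
    j <- pos + 1L
    while (j <= length(board_ids)) {
      cmp <- paired_difference(metric, ref, sub_by_id[[eid]],
                               sub_by_id[[board_ids[j]]],
                               n_boot = n_boot, seed = seed, alpha = alpha)
      if (cmp$significant) {
        out[eid] <- board_ids[j]
        break
      }
      j <- j + 1L
    }
  }
  out
}

#' Export a leaderboard
#'
#' Writes the leaderboard either as CSV (one row per entry) or as JSON
#' carrying, per entry and metric, the point value, CI bounds, per-rater
#' breakdown, and the bootstrap reproducibility metadata (`n_boot`, `seed`).
#'
#' @param board a [build_leaderboard()] result.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_leaderboard <- function(board, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(board), path, row.names = FALSE, quote = FALSE)
  } else {
    entries <- attr(board, "entries")
    payload <- lapply(entries, function(e) {
      wrap <- function(m) {
        list(value = m$value, ci_low = m$ci_low, ci_high = m$ci_high,
             level = m$level, n_boot = m$n_boot, n_dropped = m$n_dropped,
             seed = m$seed, per_rater = as.list(m$per_rater))
      }
      list(team = e$team, entry_id = e$entry_id,
           avg_pk = wrap(e$avg_pk), avg_icc = wrap(e$avg_icc))
    })
    jsonlite::write_json(list(leaderboard = payload), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
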