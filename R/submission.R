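#' Construct a submission (one score per patch)
#'
#' @param team team name.
#' @param entry_id identifier of this entry (a team may submit several).
#' @param scores named numeric vector, `names(scores)` are patch ids.
#' @return object of class `submission`.
#' @examples
#' submission("teamA", "run1", c(p1 = 0.1, p2 = 0.7))
#' @export
submission <- function(team, entry_id, scores) {
  if (is.null(names(scores)) || any(names(scores) == "")) {
    stop_validation("submission scores must be named by patch_id",
                    "pkeval_type_error")
  }
  if (anyDuplicated(names(scores))) {
    stop_validation("duplicate patch_id in submission scores",
                    "pkeval_duplicate_error")
  }
  structure(list(team = as.character(team), entry_id = as.character(entry_id),
                 scores = scores),
            class = "submission")
}

#' @export
print.submission <- function(x, ...) {
  cat(sprintf("Submission %s/%s: %d patch scores\n",
              x$team, x$entry_id, length(x$scores)))
  invisible(x)
}

#' Read a submission CSV
#'
#' The challenge submission format: a header row then one `patch_id,score`
#' row per patch, with scores as decimal fractions in \[0, 1\]. Use
#' [validate_submission()] first when the file comes from an untrusted
#' source; this reader errors on malformed content.
#'
#' @param path CSV path with columns `patch_id`, `score`.
#' @param team,entry_id labels attached to the submission.
#' @return a [submission()].
#' @export
read_submission <- function(path, team = basename(path), entry_id = team) {
  if (!file.exists(path)) {
    stop_validation(sprintf("submission file not found: %s", path),
                    "pkeval_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patch_id", "score") %in% names(df))) {
    stop_validation("submission CSV must have columns patch_id, score",
                    "pkeval_format_error")
  }
  sc <- suppressWarnings(as.numeric(df$score))
  if (anyNA(sc)) {
    stop_validation("non-numeric score in submission", "pkeval_format_error")
  }
  submission(team, entry_id, stats::setNames(sc, as.character(df$patch_id)))
}

#' Validate a submitted score file against a reference set
#'
#' Non-destructive validation mirroring an automated challenge gate: the
#' file is checked for correct formatting, full patch coverage, no extra or
#' duplicated patches, and scores within \[0, 1\]. Problems are collected
#' into a report rather than raised, so an invalid file costs the submitter
#' a report, not a crash; only an unreadable file is an error.
#'
#' @param path submission CSV path (`patch_id,score` rows).
#' @param ref the [reference_set()] defining the required patch set.
#' @return object of class `validation_report` with fields `valid`,
#'   `missing_patches`, `extra_patches`, `malformed_rows` (data.frame of
#'   line and reason), `out_of_range` (data.frame of line, patch_id, score).
#'   `valid` is `TRUE` exactly when every other field is empty.
#' @export
validate_submission <- function(path, ref) {
  if (!file.exists(path)) {
    stop_validation(sprintf("submission file not found: %s", path),
                    "pkeval_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)  # accept CRLF
  malformed <- data.frame(line = integer(), reason = character(),
                          stringsAsFactors = FALSE)
  oor <- data.frame(line = integer(), patch_id = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  add_malformed <- function(line, reason) {
    malformed[nrow(malformed) + 1L, ] <<- list(line, reason)
  }

  seen <- character()
  scores <- numeric()
  if (length(lines) == 0 || !identical(tolower(trimws(lines[1])),
                                       "patch_id,score")) {
    add_malformed(1L, "missing or wrong header (expected 'patch_id,score')")
    body_start <- 1L
  } else {
    body_start <- 2L
  }
  if (length(lines) >= body_start) {
    for (i in seq(body_start, length(lines))) {
      ln <- lines[i]
      if (trimws(ln) == "") next
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        add_malformed(i, sprintf("expected 2 fields, found %d", length(parts)))
        next
      }
      id <- trimws(parts[1])
      val <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (id == "") {
        add_malformed(i, "empty patch_id")
        next
      }
      if (is.na(val)) {
        add_malformed(i, sprintf("non-numeric score '%s'", trimws(parts[2])))
        next
      }
      if (id %in% seen) {
        add_malformed(i, sprintf("duplicate patch_id '%s'", id))
        next
      }
      seen <- c(seen, id)
      scores[id] <- val
      if (val < 0 || val > 1) {
        oor[nrow(oor) + 1L, ] <- list(i, id, val)
      }
    }
  }

  missing <- setdiff(ref$patches$patch_id, seen)
  extra <- setdiff(seen, ref$patches$patch_id)
  structure(
    list(valid = length(missing) == 0 && length(extra) == 0 &&
           nrow(malformed) == 0 && nrow(oor) == 0,
         missing_patches = missing,
         extra_patches = extra,
         malformed_rows = malformed,
         out_of_range = oor),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("Submission is VALID\n")
  } else {
    cat("Submission is INVALID\n")
    if (length(x$missing_patches)) {
      cat(sprintf("  missing patches (%d): %s\n", length(x$missing_patches),
                  paste(utils::head(x$missing_patches, 5), collapse = ", ")))
    }
    if (length(x$extra_patches)) {
      cat(sprintf("  extra patches (%d): %s\n", length(x$extra_patches),
                  paste(utils::head(x$extra_patches, 5), collapse = ", ")))
    }
    if (nrow(x$malformed_rows)) {
      cat(sprintf("  malformed rows: %d (first at line %d: %s)\n",
                  nrow(x$malformed_rows), x$malformed_rows$line[1],
                  x$malformed_rows$reason[1]))
    }
    if (nrow(x$out_of_range)) {
      cat(sprintf("  out-of-range scores: %d (first at line %d: %s)\n",
                  nrow(x$out_of_range), x$out_of_range$line[1],
                  format(x$out_of_range$score[1])))
    }
  }
  invisible(x)
}

## internal: submission scores aligned to a (possibly resampled) reference
aligned_scores <- function(sub, ref) {
  idx <- match(ref$patches$patch_id, names(sub$scores))
  if (anyNA(idx)) {
    stop_validation(
      sprintf("submission %s/%s does not cover every reference patch",
              sub$team, sub$entry_id),
      "pkeval_coverage_error")
  }
  unname(sub$scores[idx])
}
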