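#' Construct a multi-rater reference set of scored patches
#'
#' The reference standard for an evaluation: a set of image patches, each
#' carrying a patient-level cluster id (`case_id`, the unit the bootstrap
#' resamples), a slide id, and one tumor-cellularity score in \[0, 1\] from
#' every rater. Scores are stored as fractions; percentages belong at the
#' I/O boundary only (see [parse_reference()]).
#'
#' @param patch_id character vector of unique patch identifiers.
#' @param slide_id character vector of slide identifiers.
#' @param case_id character vector of patient (cluster) identifiers; must be
#'   non-empty strings.
#' @param scores numeric matrix of scores in \[0, 1\], one row per patch and
#'   one named column per rater.
#' @return An object of class `reference_set` with elements `patches`
#'   (data.frame of ids), `scores` (patch-by-rater matrix), and `rater_ids`.
#' @examples
#' reference_set(
#'   patch_id = c("p1", "p2", "p3"),
#'   slide_id = c("s1", "s1", "s2"),
#'   case_id  = c("A", "A", "B"),
#'   scores   = cbind(path1 = c(0, 0.4, 0.9), path2 = c(0, 0.5, 0.85)))
#' @export
reference_set <- function(patch_id, slide_id, case_id, scores) {
  patch_id <- as.character(patch_id)
  slide_id <- as.character(slide_id)
  case_id <- as.character(case_id)
  scores <- as.matrix(scores)
  if (anyDuplicated(patch_id)) {
    dup <- patch_id[duplicated(patch_id)][1]
    stop_validation(sprintf("duplicate patch_id '%s'", dup),
                    "pkeval_duplicate_error")
  }
  if (length(slide_id) != length(patch_id) ||
      length(case_id) != length(patch_id) ||
      nrow(scores) != length(patch_id)) {
    stop_validation("patch_id, slide_id, case_id and scores rows must align",
                    "pkeval_length_error")
  }
  if (any(is.na(case_id) | case_id == "")) {
    stop_validation("every patch needs a non-empty case_id (patient cluster)",
                    "pkeval_type_error")
  }
  if (is.null(colnames(scores)) || anyDuplicated(colnames(scores))) {
    stop_validation("scores must have unique rater column names",
                    "pkeval_type_error")
  }
  if (!all(is.finite(scores))) {
    stop_validation("every patch needs a finite score from every rater",
                    "pkeval_nonfinite_error")
  }
  if (any(scores < 0 | scores > 1)) {
    stop_validation("reference scores must lie in [0, 1] (fractions)",
                    "pkeval_range_error")
  }
  rownames(scores) <- patch_id
  structure(
    list(patches = data.frame(patch_id = patch_id, slide_id = slide_id,
                              case_id = case_id, stringsAsFactors = FALSE),
         scores = scores,
         rater_ids = colnames(scores)),
    class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "Reference set: %d patches, %d slides, %d patients, raters: %s\n",
    nrow(x$patches), length(unique(x$patches$slide_id)),
    length(unique(x$patches$case_id)), paste(x$rater_ids, collapse = ", ")))
  invisible(x)
}

n_patches <- function(ref) nrow(ref$patches)

## internal: subset/replicate a reference set by row index (patch ids may
## repeat under bootstrap resampling, so this bypasses the constructor)
ref_subset <- function(ref, idx) {
  structure(
    list(patches = ref$patches[idx, , drop = FALSE],
         scores = ref$scores[idx, , drop = FALSE],
         rater_ids = ref$rater_ids),
    class = "reference_set")
}

#' Read a reference CSV
#'
#' Expected columns: `patch_id`, `slide_id`, `case_id`, then one column per
#' rater. Rater columns hold fractions in \[0, 1\] by default; a column
#' named `<rater>.percent` (or `unit = "percent"`) is read as 0-100 and
#' converted to a fraction.
#'
#' @param path CSV file path.
#' @param unit default unit for unsuffixed rater columns: `"fraction"` or
#'   `"percent"`.
#' @return a [reference_set()].
#' @export
parse_reference <- function(path, unit = c("fraction", "percent")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    stop_validation(sprintf("reference file not found: %s", path),
                    "pkeval_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patch_id", "slide_id", "case_id")
  if (!all(need %in% names(df))) {
    stop_validation(
      sprintf("reference CSV must have columns %s", paste(need, collapse = ", ")),
      "pkeval_format_error")
  }
  if (anyDuplicated(df$patch_id)) {
    dup <- df$patch_id[duplicated(df$patch_id)][1]
    line <- which(df$patch_id == dup)[2] + 1L  # +1 for the header row
    stop_validation(
      sprintf("duplicate patch_id '%s' at line %d", dup, line),
      "pkeval_duplicate_error")
  }
  rater_cols <- setdiff(names(df), need)
  if (length(rater_cols) == 0) {
    stop_validation("reference CSV has no rater score columns",
                    "pkeval_format_error")
  }
  scores <- sapply(rater_cols, function(cl) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) {
      stop_validation(
        sprintf("missing or non-numeric score in rater column '%s'", cl),
        "pkeval_format_error")
    }
    col_unit <- if (grepl("\\.percent$", cl)) "percent"
                else if (grepl("\\.fraction$", cl)) "fraction"
                else unit
    if (col_unit == "percent") v / 100 else v
  })
  colnames(scores) <- sub("\\.(percent|fraction)$", "", rater_cols)
  reference_set(df$patch_id, df$slide_id, df$case_id, scores)
}

#' Write a reference set to CSV
#'
#' Inverse of [parse_reference()]: scores are written as fractions, so
#' `parse_reference(write_reference(ref, f))` round-trips exactly (up to
#' decimal printing precision of the scores).
#'
#' @param ref a [reference_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  df <- cbind(ref$patches,
              as.data.frame(ref$scores, row.names = NULL))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
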