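#' Tie-aware pair counting for paired score vectors
#'
#' Tallies all \eqn{n(n-1)/2} unordered pairs of items scored by a reference
#' and by an algorithm into five mutually exclusive classes: concordant
#' (`C`, both orderings strictly agree), discordant (`D`, strictly disagree),
#' tied only in the algorithm scores (`TA`), tied only in the reference
#' scores (`TR`), and tied in both (`TB`). Every rank-based metric in this
#' package — prediction probability and Kendall's tau-b — is a function of
#' these counts.
#'
#' Ties are exact floating-point equality; no tolerance is applied. Pairs
#' tied in both vectors are counted once, in `TB`, and excluded from `TA`
#' and `TR`, so that tau-b computed from these counts coincides with the
#' standard tie-corrected tau-b and a constant submission yields a
#' prediction probability of exactly 0.5.
#'
#' The counting runs in O(n log n) via a merge-sort inversion count and is
#' exactly equal to exhaustive pair enumeration.
#'
#' @param ref_scores numeric vector of reference scores.
#' @param alg_scores numeric vector of algorithm scores, same length.
#' @return An object of class `pair_counts`: a list with fields `n_items`,
#'   `C`, `D`, `TA`, `TR`, `TB`. The five pair classes always sum to
#'   `n_items * (n_items - 1) / 2`.
#' @examples
#' count_pairs(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.3, 0.2, 0.4))
#' @seealso [pk_from_counts()], [tau_b_from_counts()]
#' @export
count_pairs <- function(ref_scores, alg_scores) {
  if (!is.numeric(ref_scores) || !is.numeric(alg_scores)) {
    stop_validation("scores must be numeric vectors", "pkeval_type_error")
  }
  if (length(ref_scores) != length(alg_scores)) {
    stop_validation(
      sprintf("length mismatch: %d reference vs %d algorithm scores",
              length(ref_scores), length(alg_scores)),
      "pkeval_length_error")
  }
  if (length(ref_scores) < 2L) {
    stop_validation("at least 2 scored items are required to form a pair",
                    "pkeval_size_error")
  }
  if (!all(is.finite(ref_scores)) || !all(is.finite(alg_scores))) {
    stop_validation("scores must be finite (no NA/NaN/Inf)",
                    "pkeval_nonfinite_error")
  }
  counts <- count_pairs_cpp(as.numeric(ref_scores), as.numeric(alg_scores))
  structure(
    list(n_items = length(ref_scores),
         C = counts[["C"]], D = counts[["D"]], TA = counts[["TA"]],
         TR = counts[["TR"]], TB = counts[["TB"]]),
    class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  total <- x$n_items * (x$n_items - 1) / 2
  cat(sprintf(
    "Pair counts over %d items (%s pairs)\n", x$n_items,
    format(total, big.mark = ",")))
  cat(sprintf("  concordant (C):        %s\n", format(x$C)))
  cat(sprintf("  discordant (D):        %s\n", format(x$D)))
  cat(sprintf("  tied in algorithm (TA): %s\n", format(x$TA)))
  cat(sprintf("  tied in reference (TR): %s\n", format(x$TR)))
  cat(sprintf("  tied in both (TB):      %s\n", format(x$TB)))
  invisible(x)
}

as_pair_counts <- function(x) {
  if (inherits(x, "pair_counts")) return(x)
  stop_validation("expected a 'pair_counts' object (see count_pairs())",
                  "pkeval_type_error")
}
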