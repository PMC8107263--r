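# In-code fixtures: a small hand-checkable reference set and CSV writers.

tiny_reference <- function() {
  reference_set(
    patch_id = sprintf("p%d", 1:6),
    slide_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
    case_id  = c("A", "A", "A", "B", "B", "C"),
    scores   = cbind(path1 = c(0, 0.2, 0.5, 0.6, 0.9, 1),
                     path2 = c(0, 0.25, 0.45, 0.7, 0.85, 1)))
}

rater_as_submission <- function(ref, rater, team = rater) {
  submission(team, team,
             stats::setNames(ref$scores[, rater], ref$patches$patch_id))
}

write_submission_csv <- function(scores, path) {
  writeLines(c("patch_id,score",
               sprintf("%s,%s", names(scores), format(scores, digits = 15))),
             path)
  path
}
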