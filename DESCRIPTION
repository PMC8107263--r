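Package: pkeval
Title: Concordance-Based Evaluation of Continuous Tumor Cellularity Estimates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Evaluation harness for challenge-style scoring of continuous
    estimation algorithms, built around tumor cellularity (TC) scoring of
    breast histology patches after neoadjuvant treatment. Provides tie-aware
    concordant/discordant pair counting, the prediction probability (PK)
    concordance metric, Kendall's tau-b (including its vulnerability to tie
    inflation via output binning), two-way random-effects absolute-agreement
    intraclass correlation ICC(2,1), patient-clustered percentile bootstrap
    confidence intervals, paired significance comparison between algorithms,
    submission validation, leaderboards with significance frontiers,
    patch-level mean-squared-error analysis, and a fully seeded synthetic
    challenge generator so every component is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
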