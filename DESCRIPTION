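Package: reosig
Title: Rank-Based Gene-Pair Signatures for Chemotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery, application and survival-based validation of
    qualitative transcriptional signatures built from within-sample
    relative expression orderings (REOs) of gene pairs. Implements the
    full pipeline from differential-expression and prognostic screening
    through oriented gene-pair selection under false discovery rate
    control to greedy forward selection of a majority-voting gene-pair
    signature by Harrell's concordance index, together with the
    published four-pair ovarian-cancer signature (4-GPS), a
    median-anchored point-score comparator, Kaplan-Meier/log-rank/Cox
    validation reports, and a seeded synthetic-cohort generator with
    planted pairs, proportional-hazards survival, batch-effect and
    degradation perturbations for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
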