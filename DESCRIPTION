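Package: reosig
Title: Rank-Based Gene-Pair Signatures for Microsatellite Instability
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and application of qualitative transcriptional
    signatures built from within-sample relative expression orderings
    (REOs) of gene pairs, for predicting microsatellite instability (MSI)
    status of colon tumors from a single expression profile. Implements
    the full discovery pipeline (Student's t differential-expression
    screen, one-sided Fisher's exact screen on pair-order frequencies,
    the frequency-difference statistic, redundancy removal, and
    F-score-maximising vote-threshold selection), rank-only majority-vote
    classification including the published 10-gene-pair signature,
    evaluation metrics (sensitivity, specificity, harmonic-mean F-score,
    Mann-Whitney AUC, clustering-based assessment of disconfirmed
    samples), and a synthetic-data generator with planted pair structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
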