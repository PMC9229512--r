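Package: gvtnorms
Title: Normative Scoring and Norm Derivation for the Groffman Visual Tracing Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clinical scoring engine and re-runnable norm-derivation pipeline
    for the Groffman Visual Tracing (GVT) test, an oculomotor performance
    task scored for accuracy (lines followed correctly out of 10) and mean
    execution time. Implements line-uniformization corrections,
    regression-based demographic adjustment of raw scores for age, education
    and sex (with AICc transformation search and model selection),
    non-parametric one-sided tolerance limits, percentile tables, rank-based
    equivalent scores, and correction grids for clinical use. Ships the
    published adult norms and a synthetic-cohort generator so that every
    pipeline stage can be exercised and validated without access to the
    original normative cohort.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
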