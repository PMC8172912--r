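Package: cd4eqa
Title: Scoring and Longitudinal Analytics for CD4 External Quality
    Assessment Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the scoring and evaluation pipeline of a national
    external quality assessment (EQA) program for CD4 T-cell enumeration:
    trimmed consensus statistics with outlier exclusion, Standard Deviation
    Index (SDI) scoring with a +/-2 SDI pass criterion, classification of
    failures into pre-analytical, analytical and post-analytical phases,
    longitudinal participation and performance analytics, and per-laboratory
    and coordinator report generation.  A synthetic EQA-program generator
    with known ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
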