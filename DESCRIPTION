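Package: mountaincnv
Title: Arm-Wise Copy-Number Curve Profiling and Dynamic Time Warping
    Similarity for Pan-Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds gene-level copy-number matrices from segmented CNV
    ("SEG") files, profiles chromosome arms as ordered per-gene summary
    ("Mountain") curves, and scores curve similarity between sample
    groups with normalized dynamic time warping plus a pooled-resampling
    bootstrap significance test. Also computes the per-gene statistics
    behind volcano, directional Manhattan, deflection, bee-swarm and
    CNV-expression regression displays, with Benjamini-Hochberg or
    Bonferroni multiple-testing control, and ships a synthetic cohort
    generator with controlled broad and focal alterations so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
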