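Package: arecamir
Title: Areca Nut-Associated miRNA Panel Profiling and Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for deriving oncogenic and
    tumor-suppressive miRNA panels associated with chronic areca nut
    exposure in head and neck cancer. Implements signed fold-regulation
    algebra with ratio-scale panel averaging, paired cell-line
    differential profiling with an eight-region joint classification,
    tumor/normal cohort screening with stromal/immune purity estimation
    and linear de-mixing calibration, concordance integration of the two
    panels with two-axis signature selection, multi-source miRNA-target
    consensus voting with bipartite network export, hypergeometric
    pathway over-representation with phenotype-module rollup, and
    synthetic-data generators with stored ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
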