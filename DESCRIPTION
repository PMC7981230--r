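Package: traitfilter
Title: T-Statistics, Null Models and Trait-Overlap Metrics for
    Individual-Based Community Assembly Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring internal (within-community) and external
    (environmental) filters in community assembly from individual-level
    functional trait measurements. Implements the T-statistic family of
    nested variance ratios with full intraspecific trait variability,
    permutation null models with standardized effect sizes and significance
    envelopes, community-weighted means, kernel-density trait overlap
    (functional beta diversity), taxonomic and functional rarefaction,
    gradient regressions with slope comparison, and an individual-based
    community-assembly simulator with tunable filter strength for
    validation and power analysis.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
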