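Package: pestscore
Title: Contamination, Regulation and Risk Scoring of Pesticides in Global Freshwater
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing pesticide contamination of surface freshwater
    and groundwater across countries from heterogeneous monitoring data.
    Implements a deviation-from-central-tendency contamination score on
    log10-transformed site-mean concentrations with limit-of-detection
    substitution for non-detects, percentile bootstrap confidence intervals,
    water-quality-standard completeness and stringency indices over a
    30-pesticide panel, mean pesticide usage intensity, hazard-quotient
    screening of high-scoring countries, drinking-water-standard exceedance
    rates with WHO fallback, and rank-difference / Spearman association
    between score sets. A seeded synthetic-data generator with analytically
    known expected scores supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
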