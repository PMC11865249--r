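Package: faersignal
Title: Disproportionality Signal Screening for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal
    detection on spontaneous adverse-event reports in the style of the FDA
    Adverse Event Reporting System (FAERS). Provides a synthetic report
    generator with controlled demographic marginals and planted drug-event
    association strengths, quarterly-file ingestion with deduplication and
    cohort filtering, descriptive cohort summaries, drug-event 2x2
    contingency tables with four disproportionality statistics (reporting
    odds ratio with Wald interval and Fisher p-value, relative reporting
    ratio, shrunk log2 safety signal, and the BCPNN information component
    with credible bounds), three published decision rule sets, sex-by-age
    stratified screening matrices, and pairwise drug-correlation ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
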