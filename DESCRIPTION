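Package: nsindex
Title: Natural Succession Index for Evaluating Natural Restoration Across
    Climate Sub-Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how readily natural vegetation succession
    (grassland to shrub to forest) proceeds under different climate
    conditions, using long-term monitoring-plot series. Provides two-stage
    climate regionalization of towns from accumulated temperature and four
    secondary climate/terrain factors, classification of 30-year plot
    series into succession outcomes with interval-censored stage
    durations, a habitat-quality-weighted Natural Succession Index per
    sub-area, and an index-driven re-balancing of restoration budgets
    around the mean index. A seeded synthetic-data generator emulates the
    monitoring system so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
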