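Package: skintrends
Title: Benchmark-Anchored Analysis of Search Interest in Skin Problems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infodemiology studies built on Google Trends relative
    search volume (RSV) exports: parsing of interest-over-time and
    compared-breakdown-by-region CSVs with censored-value imputation,
    benchmark-anchored cross-topic popularity scaling against a reference
    topic, per-country topic rankings with low-search-volume exclusion,
    secular-trend inference (Seasonal Mann-Kendall test and ordinary
    least-squares slope in RSV per year), additive seasonal decomposition by
    local polynomial regression with a periodic seasonal component and
    peak/trough/amplitude summaries, and a seeded synthetic-data generator
    emulating the Google Trends observation process (joint max-100 rescaling,
    integer rounding, censoring, region shares, low-volume masking) with
    known ground truth. Ships a topic registry for dermatologic clinical
    signs and an end-to-end analysis pipeline producing popularity, trend,
    seasonality, and country-winner tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
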