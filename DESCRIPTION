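Package: malefert
Title: Male Total Fertility Rates from Female Fertility and Adult Sex Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sex differences in total fertility rates.
    Estimates male total fertility rates (TFR) indirectly from female TFR and
    reproductive-age sex ratios with a log-log regression and 90% prediction
    intervals; computes demographically standardized male TFRs by applying
    births by maternal age to the male population structure; decomposes period
    age-specific population sex ratios into a sex-ratio-at-birth contribution
    and a cumulative sex-differential survivorship contribution; detects male
    to female fertility crossovers and summarizes country shares; and ships a
    migration-free cohort-component scenario generator that produces internally
    consistent population, birth, life-table and fertility tables with known
    ground truth for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
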