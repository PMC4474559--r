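Package: dispaq
Title: Between-Country Life-Expectancy Disparity Metrics for Regional Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying between-country disparities in life
    expectancy at birth from country-period panels. Computes
    population-weighted regional life expectancy, gap and shortfall series
    against world and best-performing comparators, gender disparity
    summaries, and a six-metric suite of absolute and relative disparity
    measures (range difference and ratio, mean difference from best, index
    of disparity, between-group variance, and the symmetric Theil index).
    Includes percent-change trend reporting, leave-one-out region-membership
    sensitivity analysis, and a synthetic panel generator that emulates the
    structure of United Nations demographic projections for fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
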