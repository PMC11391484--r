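Package: hrequity
Title: Equity of Health Workforce Allocation Across Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the level and equity of health human
    resource allocation across administrative regions from provincial
    panel data. Implements the health resource density index (the
    geometric mean of staff per population and staff per land area),
    population- and area-weighted Lorenz curves and Gini coefficients
    for grouped data, and the Theil entropy index with an exact
    between-/within-region decomposition and contribution rates.
    Includes a log-normal synthetic panel generator with tunable
    allocation inequality, published reference tables for China's
    provincial CDC workforce (2016-2020) as worked fixtures, and a
    report pipeline that reproduces the standard table shapes of
    health-resource equity studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
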