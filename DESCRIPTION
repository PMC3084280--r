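Package: smtrend
Title: Statistical Meaningfulness Tests for Linear Time Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a linear time trend is statistically meaningful,
    a stricter quality criterion than significance alone: a series is
    meaningful when the regression of time against the series itself, or
    against interval mean values from any division of the series into k
    consecutive intervals, attains a coefficient of determination of at
    least 0.65 at a two-tailed p-value of at most 0.05. Implements the two
    interval-division methods (fractional unit-cell weighting for regularly
    spaced series, equal time sub-ranges for irregular ones), the
    r-squared/t/p statistical kernel for bivariate trend regressions,
    sensitivity analysis over threshold grids, and a Monte Carlo harness
    that characterises the behaviour of the test across division counts.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
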