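Package: percentileCI
Title: Exact and Approximate Confidence Intervals for Normal Percentiles
    and Limits of Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Interval estimation and study planning for normal percentiles,
    with the Bland-Altman 95% limits of agreement as the motivating
    application. Provides the exact confidence interval based on the
    noncentral t pivotal quantity, the Chakraborti-Li and Bland-Altman
    approximate intervals, sample-size determination under expected-width
    and assurance-probability precision criteria, and a Monte-Carlo
    harness for evaluating one- and two-sided coverage of all three
    procedures. Includes a synthetic paired-measurement generator, CSV
    input for method-comparison data, tidy() and glance() accessors, and
    ggplot2 visualisations of coverage errors and sample-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
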