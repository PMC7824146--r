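Package: wishindex
Title: Diet-Quality and Sustainability Scoring with the World Index for
    Sustainability and Health (WISH)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores dietary intake data against the World Index for
    Sustainability and Health (WISH), a 13-component diet-quality index built
    on the EAT-Lancet reference diet. Each food group receives a 0-10
    piecewise-linear adherence score; components sum to a 0-130 total and four
    sub-scores (healthy, less-healthy, low and high environmental impact).
    Includes readers for per-recall intake tables with recall-day averaging,
    food-item to food-group mapping, population summaries (mean scores,
    non-consumer percentages, direction-of-change labels), a Spearman
    correlation analysis of score drivers, and a seeded zero-inflated
    lognormal simulator of 24-hour-recall intake data calibrated to published
    population parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
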