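Package: menuswap
Title: Strategic Weekly Menu Optimization from Pairwise Food Preferences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the effect of strategically rearranging dishes across a
    weekly catering menu (5 days x 3 options, 15 dishes) on cohort-level
    carbon footprint and saturated-fat intake. Converts two-alternative
    forced-choice (2AFC) trial data into per-participant win-count rankings,
    exhaustively enumerates all weekly menus (partitions of the dish set
    into five unordered days of three) under a minimum-vegetarian-per-day
    constraint, predicts each participant's daily choice as the top-ranked
    offered dish, and selects menus minimizing mean weekly carbon footprint,
    saturated-fat intake, or an equal-weight combination of both, reported
    as percent change versus a baseline menu. Includes a synthetic-cohort
    generator (correlated log-normal dish attributes, latent-utility
    Bradley-Terry responders) so the full pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
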