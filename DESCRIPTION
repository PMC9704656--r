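Package: marshflood
Title: Tidal Inundation Hydroperiod and Porewater Nutrient Trends in Salt
    Marshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links sea-level-rise-driven tidal inundation to porewater
    nutrient trends in salt marsh monitoring programmes. Computes plot-level
    hydroperiod metrics (annual hours inundated, flooding events, percent of
    year flooded, Mean Higher High Water) from regularly sampled water-level
    series referenced to a common vertical datum, fits plot-level linear
    trends in inundation and porewater chemistry, compares marsh zones
    between years with nested linear mixed-effects models (with Nakagawa
    marginal and conditional R-squared), and regresses nutrient rates of
    change on inundation rates of change across plots. Includes a synthetic
    tide, marsh-transect and porewater generator with known ground truth so
    the whole pipeline can be exercised and calibrated without external
    data, plus readers and writers for tide-gauge style six-minute CSV,
    plot tables and long-format porewater tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
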