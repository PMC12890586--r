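Package: forestshift
Title: Tree Species Richness Change Across Long-Term Forest Census Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and explain change in tree species richness
    across networks of permanent forest inventory plots. Provides census
    ingestion and taxonomic standardization, plot eligibility filtering and
    small-plot grouping, per-plot diversity and demographic statistics
    (richness change, stem abundance change, interval-corrected mortality,
    individual-based rarefaction), climate baseline and trend covariates,
    landscape tree-cover integrity, balanced region-stratified bootstrap
    t-tests and regressions, and a multigroup piecewise structural equation
    model with directed-separation tests, Fisher's C and indirect-effect
    decomposition. Includes a synthetic census, climate and landscape
    generator with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    rlang,
    vegan,
    geosphere,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    lmtest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
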