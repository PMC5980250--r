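Package: lactofat
Title: Milk Fatty-Acid Panel Summarisation and Dietary Omega-6/Omega-3 Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for censoring-aware summarisation of bulk-tank milk
    fatty-acid panels (below-limit-of-detection handling, Tukey-fence outlier
    screening, regional and seasonal group means), fat-standardised comparison
    of milk types (conventional, organic, grass-fed), a dietary linoleic to
    alpha-linolenic acid (LA/ALA) scenario model over fat level, dairy-serving
    level, dairy fat source and nondairy fat composition, and a daily
    fatty-acid contribution calculator for dairy servings versus fish. Includes
    a seeded synthetic panel generator with farm, region and seasonal structure
    for parameter-recovery testing.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
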