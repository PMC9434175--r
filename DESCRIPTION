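Package: sgascreen
Title: Analysis of Synthetic Genetic Array Colony-Size Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synthetic sick/lethal (SL) and synthetic
    dosage lethal (SDL) genetic-interaction screens performed by synthetic
    genetic array (SGA). Covers plate layout construction for the standard
    384/768/1536 colony densities (replicated array positions, border
    controls, blanks, duplicate pinning), spatial normalization of colony
    sizes, single- and double-mutant fitness estimation, multiplicative-model
    interaction scores with linkage and replicate filtering, derived and
    fixed hit-calling thresholds, screen summaries, cross-screen comparison,
    and score-matrix export. A synthetic-screen generator with planted
    single-mutant fitness defects, pairwise interaction effects, spatial
    biases and lognormal colony noise makes the whole pipeline testable
    without access to raw plate images.
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
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
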