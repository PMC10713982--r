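Package: morphodyn
Title: Comparative Morphodynamics of Developing Tissues in Rescaled Spacetime
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs continuous two-dimensional tissue deformation maps
    from sparse labeled-cell correspondences, decomposes them into average
    growth and size-free (rescaled, xi-space) dynamics, synchronizes
    developmental clocks between species by trajectory matching, and
    quantifies cross-species conservation of morphogenetic flow with
    region-restricted fit and overfitting statistics. Includes a two-species
    synthetic-data generator that plants a shared archetype flow under
    species-specific growth schedules and stage warps, so the whole pipeline
    is testable without measurement data.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
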