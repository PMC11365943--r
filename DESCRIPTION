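Package: vertregions
Title: Regionalization, Homologous Modules, and Serial Disparity of the
    Vertebral Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies regionalization of serially homologous vertebral
    columns from per-vertebra morphometric tables. Cleans raw measurement
    tables (absent and broken apophyses), ordinates vertebrae by principal
    coordinates analysis on Gower distances, fits continuous segmented
    linear regressions over ordination axes with BIC model averaging to
    estimate region numbers, breakpoints and a continuous region score,
    classifies vertebrae into homologous modules by spectral clustering in
    a common morphospace, computes serial disparity, and relates these
    metrics to ecology with phylogenetic generalized least squares and
    phylogenetic ANOVA under Pagel's lambda. Includes a synthetic-data
    generator with planted region structure, simulated phylogenies and
    trait evolution so the whole pipeline is testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    cluster,
    phytools
Config/testthat/edition: 3
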