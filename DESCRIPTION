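Package: woodgrad
Title: Vertical Wood-Density Gradients and Bias-Corrected Tree Biomass
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing vertical wood-density gradients within
    trees and for correcting the systematic bias these gradients induce when
    tree volumes (destructive or LiDAR-derived) are converted into
    aboveground biomass. Implements the volume-weighted wood density (VWWD)
    estimator, laboratory-to-field processing of destructive sampling data
    (wedge samples, weighed and coned logs), scaled PCA ordination of
    relative wood-density profiles with supplementary-variable correlations,
    bias and total-error statistics with a family of linear VWWD correction
    models and leave-one-site-out cross-validation, guild and taxonomic
    analyses including Blomberg's K with tip-randomization tests, and a
    synthetic-data generator emulating the statistical structure of
    multi-site destructive sampling campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
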