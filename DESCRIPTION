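Package: biofilmpulse
Title: Stochastic Sigma-Factor Pulsing and Spatial Patterning in
    Bacterial Biofilms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how stochastic pulsing of the general
    stress response sigma factor sigma-B can pattern Bacillus subtilis
    biofilms. Implements an exact Doob-Gillespie simulator for a
    two-regulator transcription-translation network in which the stress
    regulator represses the sporulation regulator, spore-decision rules
    based on sustained threshold crossings, replicate ensembles swept
    across a stress gradient, closed-form moment and truncated
    master-equation oracles for validating the simulator, a synthetic
    multi-channel biofilm cross-section image generator with per-cell
    ground truth, and an image-quantification pipeline: biofilm
    segmentation (Otsu, seeded watershed, erosion filtering), depth maps
    from the air-facing surface, ratiometric expression gradients,
    single-cell statistics, spore-density profiles and anticorrelation
    analysis of competing reporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    ggplot2,
    graphics,
    rlang,
    jsonlite,
    mclust,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
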