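Package: vegbelt
Title: Altitudinal-Belt Stratified Sampling and Object-Based Mountain
    Vegetation Classification
Version: 0.1.0
Authors@R:
    person("Maintainer", "vegbelt", email = "vegbelt@example.org",
           role = c("aut", "cre"))
Description: Object-based image analysis (OBIA) pipeline for fine-scale
    mountain vegetation mapping driven by mountain altitudinal belt (MAB)
    prior knowledge. Provides multiresolution region-merging segmentation
    with mean-variance scale selection, terrain constraint factors
    (ridgeline slope split + belt rasterization), fully automatic
    belt-stratified training-sample selection (clustering, Pauta 3-sigma
    purification, iterative 2-cluster correction), random-forest and
    k-nearest-neighbour object classification with F1-tuned parameters,
    confusion-matrix accuracy assessment (overall/user/producer accuracy,
    Cohen's kappa), and a seeded synthetic mountain-scene generator so the
    whole pipeline is testable without satellite imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
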