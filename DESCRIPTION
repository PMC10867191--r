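Package: hexaflora
Title: Bee-Vision Colour Signals of Flowers Along Elevational Gradients
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models flower reflectance spectra (300-700 nm) through the
    hymenopteran colour hexagon to obtain chromatic colour contrast and
    achromatic green contrast for honeybee vision, and relates these
    signals and flower size across elevational zones with phylogenetic
    generalized least squares under Pagel's lambda.  Includes maximum
    likelihood estimation of lambda with profile-likelihood confidence
    intervals, AIC-based selection among linear, quadratic and
    log-predictor models, single-trait phylogenetic-signal tests, and a
    synthetic-data generator (flower-like spectra, ultrametric trees
    with polytomies, lambda-structured traits) for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils, grDevices, graphics, yaml, jsonlite
Suggests: testthat (>= 3.0.0), phytools, nlme, pracma, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
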