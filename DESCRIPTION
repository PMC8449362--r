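Package: tomopod
Title: Synthetic Cryo-Electron Tomography Analysis of Platelet Pseudopodia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic cryo-electron tomograms of platelet
    pseudopodia with known ground truth (helical actin filaments of mixed
    polarity bundled inside a membrane tube on a support film, membrane-
    attached receptor densities, additive noise and a single-axis missing
    wedge) and re-implements the two in-situ analyses these scenes are built
    to exercise: per-filament actin polarity determination from masked slab
    projections, in-plane alignment, reference-free 2D classification and
    helical-model template matching, aggregated into tip-ward/cell-ward
    polarity fractions with an exact binomial confidence criterion; and
    membrane-attached particle picking with height-above-support and
    normal-tilt filters, oriented subtomogram averaging and 3D
    classification, receptor height measurement, rigid-body map fitting and
    a Monte-Carlo spatial-randomness test. Includes MRC volume and TSV/STAR
    table input/output and half-set Fourier shell correlation resolution
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
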