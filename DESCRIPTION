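Package: mechq
Title: Quantification of Cellular Contractility, Nuclear Dynamics, and
    Morphometry from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers cell-generated traction stresses and strain energy from
    fiducial-bead displacements by Tikhonov-regularized Fourier-transform
    traction cytometry on a linear-elastic half-space, quantifies chromatin and
    nuclear dynamics through Pearson-correlation decorrelation curves fitted
    with a three-parameter exponential decay model, and provides morphometric
    read-outs used in fibroblast contractility studies: DNA-damage foci per
    nucleus, region intensity measures, EdU-positive fractions, spheroid sprout
    lengths from skeletonized micrographs, collagen-gel contraction, and
    delta-delta-Ct fold changes. Seed-reproducible synthetic-data generators
    supply ground truth for every stage, so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    igraph,
    clue,
    interp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
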