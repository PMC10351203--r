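Package: pvsmorph
Title: Morphometry and Hydraulic Resistance of Pial Perivascular Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying the size, shape and
    hydraulic resistance of pial perivascular spaces (PVS) imaged with in
    vivo two-photon microscopy. The package segments vessel and CSF-tracer
    channels of 3D fluorescence stacks with depth-varying intensity
    thresholds, extracts centerline-normal cross sections, fits idealized
    cross-section geometries (circle, elliptical annulus, spline, and
    two-lobed polynomial shapes), solves fully developed Poiseuille flow on
    each cross section to obtain hydraulic resistance per unit length, and
    summarizes parameter distributions. A synthetic-stack generator with
    exact ground-truth geometry makes every stage testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
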