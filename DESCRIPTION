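Package: optmorph
Title: Quantitative Optical Projection Tomography of Cells in 3D Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, reconstruction and quantification pipeline for
    optical projection tomography (OPT) of cells embedded in transparent
    3D hydrogel scaffolds. Generates cell-laden digital phantoms with
    known ground truth, simulates parallel-beam projection acquisition,
    normalizes projection brightness with a homomorphic filter,
    reconstructs volumes by filtered back-projection with
    center-of-rotation correction, segments cells by thresholding and 3D
    morphology, and quantifies per-cell morphology (equivalent-ellipsoid
    elongation and flatness), sample density, and live/dead viability,
    with a gated parametric/non-parametric group-comparison layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
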