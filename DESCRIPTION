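Package: aaafsi
Title: Fluid-Structure Interaction Modeling of Abdominal Aortic Aneurysms
    with Pre-Stress Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale framework for patient-specific fluid-structure
    interaction (FSI) simulation of abdominal aortic aneurysms (AAA) from
    ultrasound-style contour-stack segmentations. Builds quadratic
    hexahedral vessel-wall meshes from stacked elliptical lumen contours,
    solves incompressible Neo-Hookean wall mechanics with follower pressure
    loading and Backward-Incremental pre-stress estimation, couples the
    wall to a reduced-order pulsatile lumen flow model terminated by a
    patient-tuned three-element Windkessel, and post-processes wall shear
    (TAWSS, OSI) and wall-mechanics metrics comparing simulations with and
    without pre-stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
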