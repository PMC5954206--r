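Package: reappose
Title: Re-Apposition Pressures for Aortic Dissection Flaps from a
    Hyperelastic Cross-Section Contact Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the biomechanics of Stanford type-B aortic dissection
    repair. Implements the dispersed two-fiber-family (Gasser-Ogden-Holzapfel)
    anisotropic hyperelastic constitutive model for aortic tissue, estimates
    its parameters from planar biaxial stress-stretch data by multi-start
    Nelder-Mead regression, generates synthetic biaxial datasets and material
    variants for simulation studies, and solves a quasi-static finite-strain
    plane-strain contact problem in which a rigid expansion member (a
    balloon or stent analog) re-apposes the intimal flap of a dissected
    porcine thoracic aorta against the false-lumen wall under static aortic
    pressure. Reports the radial re-apposition pressure and final lumen
    diameter over a 70-140 mmHg pressure sweep for mid and distal dissection
    regions, with mesh-convergence and material-sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    lhs,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
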