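Package: lvmech
Title: Finite-Element Mechanics of Transmural Contractility in an Idealized Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quasi-static finite-element simulation of a human left ventricle
    idealized as a truncated thick-walled ellipsoid. Implements the
    Holzapfel-Ogden anisotropic hyperelastic passive law, a time-varying
    active-tension model with length-dependent calcium sensitivity, rule-based
    transmural myofiber orientation, calibration of passive stiffness to the
    Klotz single-point end-diastolic pressure-volume relation, calibration of
    contractility to a measured end-systolic volume, and a lumped two-element
    Windkessel afterload. Provides scenario machinery for transmural
    contractility experiments (subendocardial dysfunction, subepicardial
    compensation) and post-processing of ejection fraction, torsion, global
    strains, sphericity, and transmural fiber strain and stress profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo, Matrix
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
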