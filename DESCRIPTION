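Package: kbsim
Title: Virtual Ultrasound-Guided Kidney Biopsy Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a virtual ultrasound-guided kidney biopsy
    trainer. Couples a corotational linear-tetrahedral finite-element model of
    the kidney, stepped with implicit backward Euler under projected Dirichlet
    constraints, to a rigid-line needle with lateral spring coupling, axial
    friction and a capsule-puncture state machine. Produces a haptic force
    channel (zeroth-order-hold resampling with optional moving-average
    smoothing) and a resliced ultrasound view with deformation warping and a
    synthetic needle echo overlay. Ships a speckled synthetic kidney phantom
    (volume plus matched tetrahedral mesh) and scripted probe/needle
    trajectories so full biopsy sessions run deterministically with no
    tracking hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
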