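Package: ocmotion
Title: Optimal Control Reconstruction of Measured Human Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs measured whole-body movements as dynamically
    consistent optimal control simulations of 3D musculoskeletal models by
    directly tracking marker trajectories and ground reaction forces, or by
    tracking generalized coordinates estimated with inverse kinematics.
    Implements direct collocation with an implicit formulation of the
    multibody, muscle activation and muscle contraction dynamics discretized
    by backward Euler, a penetration-based foot-ground contact model, static
    standing calibration of the contact geometry, and the classical inverse
    kinematics / inverse dynamics pipeline with pelvis residual analysis used
    as baseline. Includes readers and writers for TRC and STO/MOT motion
    files, gait event detection, a synthetic motion-capture data generator
    with ground truth, and evaluation utilities (RMSD, body-weight and
    GRF-max scalings, convergence reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
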