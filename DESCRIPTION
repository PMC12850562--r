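Package: sodiumgate
Title: Self-Gated Motion-Resolved 3D Radial MRI: Simulation, Gating,
    Reconstruction and RF-Safety Arithmetic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for respiratory self-gated 3D center-out radial
    (koosh-ball) MRI of X-nuclei such as sodium-23. Generates 2D
    golden-means radial trajectories with density compensation, simulates
    a programmable respiratory motion phantom acquired with an 8-channel
    transceiver array, extracts a respiratory surrogate from repeated
    k-space-center (self-gating) samples, bins excitations into motion
    states and reconstructs them with Kaiser-Bessel gridding and
    sensitivity-weighted (SENSE1) channel combination. Includes an
    edge-spread logistic fit as a relative-resolution readout, NRMSE and
    gating-correlation metrics, and the RF-safety arithmetic used to
    derive total power limits from thermometry and simulated peak 10 g
    SAR values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    rhdf5,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
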