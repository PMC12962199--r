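Package: lungshim
Title: Automated 2D Lung Shimming from TR-Shifted Multi-Echo Gradient-Echo MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and inline processing for rapid, automated 2D shimming
    of the lung at 3T. Generates synthetic coronal thorax phantoms with
    ultra-short lung T2* and structured off-resonance, simulates TR-shifted
    multi-echo gradient-echo acquisitions with respiratory motion, and
    implements the full shim-calibration chain: non-rigid registration and
    complex averaging, classical lung segmentation, voxel-wise field mapping
    from incremental echo phases, mask-restricted spherical-harmonic shim
    current estimation (zeroth to second order, coronal y = 0 convention), and
    evaluation of the predicted residual field including balanced steady-state
    free precession (bSSFP) off-resonance response and banding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
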