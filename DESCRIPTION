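Package: marbench
Title: Benchmarking Iterative Metal Artifact Reduction for Particle Therapy CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthetic end-to-end evaluation of iterative metal artifact
    reduction (iMAR-style NMAR + FSMAR) for carbon-ion treatment planning on
    pelvic CT with hip prostheses. Generates a digital anthropomorphic pelvic
    phantom with optional unilateral or bilateral metal implants, simulates
    parallel-beam CT acquisition with beam hardening and photon starvation,
    reconstructs by filtered back projection, applies an iterated
    normalized-sinogram-inpainting (NMAR) and frequency-split (FSMAR)
    correction, converts CT numbers to relative linear stopping power through
    a piecewise-linear calibration curve, and quantifies the impact on
    water-equivalent path length, surrogate spread-out-Bragg-peak dose
    distributions, gamma pass rates, dose-volume histogram statistics and
    region-of-interest CT-number accuracy against the artifact-free ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
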