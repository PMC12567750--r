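Package: fnirscal
Title: Monte Carlo Depth-Sensitivity Calibration for fNIRS Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates near-infrared photon transport through layered head
    phantoms with a packet-based Monte Carlo engine, computes depth-resolved
    sensitivity (SAD) profiles from the fluence volumes, fits Gaussian-process
    and support-vector surrogates of sensitivity over source-detector
    separation and cortical depth, and inverts the surrogate to recommend
    region-specific probe separations for functional near-infrared
    spectroscopy (fNIRS) experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    RNifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
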