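Package: orthotrack
Title: Markerless Tumor Tracking with Orthogonal kV Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for markerless real-time tumor tracking with an
    orthogonal kV X-ray imaging system rotating with the gantry: digitally
    reconstructed radiograph (DRR) rendering by Siddon ray tracing, a
    synthetic 10-phase breathing-thorax phantom with analytic ground truth,
    angle-perturbation augmentation and GTV contour label generation,
    a pluggable per-tube-angle contour predictor with a deterministic
    template-matching reference backend, orthogonal-ray midpoint
    triangulation of 3D tumor positions, and the evaluation statistics
    (3D deviation distributions, prediction rates, Pearson correlations)
    used to assess such systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    pracma,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
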