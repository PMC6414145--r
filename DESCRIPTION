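Package: epidose
Title: Transit Dosimetry with Portal Images: Thickness Calibration,
    Motion Simulation and Gamma Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the effect of respiratory motion on
    transit dosimetry with an electronic portal imaging device (EPID).
    Portal images are converted to equivalent water-equivalent plastic
    thickness maps with a per-pixel quadratic attenuation calibration and
    an iterative field-size/scatter correction.  Motion effects are
    quantified with per-pixel dose-difference statistics and a local-dose
    two-dimensional gamma analysis inside a segmented region of interest.
    A synthetic phantom, beam and frame-integrated acquisition simulator
    generates calibration slab series and motion-blurred treatment images
    so the whole chain runs without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
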