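Package: usneedle
Title: Photoacoustic-Supervised Needle Segmentation and Tracking in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for needle tracking in B-mode ultrasound with photoacoustic
    (PA) ground truth. Forms ultrasound and PA images from beamformed RF
    (quadrature demodulation, Hilbert envelope, log compression), derives
    binary needle ground-truth masks from PA frames by thresholding,
    connected-component labeling and largest-component selection, trains
    nested-U segmentation networks (UIU-Net and reference U-Net variants,
    implemented natively with compiled convolution kernels) to enhance needle
    visibility in ultrasound images, and scores predictions with needle
    localization success rate, Modified Hausdorff Distance, targeting error
    and needle length ratio. A paired US/PA simulator of in-plane needle
    insertion with speckle, echo dropout, reverberation ghosts and PA absorber
    artifacts makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
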