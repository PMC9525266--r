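Package: lapreg
Title: Feature-Based Registration of Laparoscopic Video for Spectral Image Overlay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers a saved reference ("start") frame of a laparoscopic video
    against subsequent frames so that static physiological maps, such as
    tissue-oxygenation images derived from hyperspectral imaging, can be
    overlaid on live video. Implements glare-masked green-channel
    preprocessing, binary-descriptor keypoint matching with crosscheck,
    robust single-homography estimation (RANSAC), hierarchical multi-affine
    region transforms, affine moving-least-squares deformation fields,
    per-pixel candidate fusion with display masking, a ground-truth
    evaluation protocol (reprojection error, normalized reprojection error,
    SSIM), CVAT annotation XML I/O, and a synthetic phantom generator with
    exact ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    xml2,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
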