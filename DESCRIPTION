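Package: minimalml
Title: Minimalist Machine Learning for Two-Class Feature and Image Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the minimalist machine learning (MML) two-class
    classifier: attribute relevance ranking by class-mean differences
    (dMeans), projection of each pattern onto its (standard deviation,
    mean) pair over the selected attribute prefix, and a horizontal
    hypothesis-line decision rule.  Includes a grayscale CT-style image
    enhancement and segmentation chain (contrast-limited adaptive
    histogram equalization, mean/median smoothing, intensity-threshold
    skull removal, band segmentation of candidate hemorrhage regions,
    binary morphology, superimposition and flattening), a leave-one-out
    cross-validation harness with confusion-matrix metrics, and seeded
    generators for synthetic two-class feature tables and phantom head
    images so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    grDevices,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
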