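Package: mammotex
Title: Texture-Feature Pipeline for Multiclass Mammogram Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for grayscale medical
    images, built around five gray-level texture descriptor families
    (co-occurrence, local binary patterns, LBP co-occurrence, run-length,
    and segmentation-based fractal texture analysis) that together yield
    an 88-dimensional feature vector per image.  Class imbalance is
    handled by adaptive synthetic (ADASYN) oversampling, feature
    selection by ReliefF weighting, and classification by a feedforward
    neural network trained with the Levenberg-Marquardt algorithm.
    Includes per-class confusion-matrix metrics, a seeded synthetic
    texture and tabular data generator, and readers for PNG, TIFF and
    uncompressed DICOM images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    caret,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
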