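Package: leafnitro
Title: Leaf Nitrogen Estimation from RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates leaf nitrogen content from RGB photographs of single
    leaves taken against a white board. Provides multi-scale retinex
    illumination correction with color restoration (MSRCR), whiteboard
    background segmentation, extraction of 24 color features across four
    color spaces and 5 gray-level co-occurrence matrix (GLCM) texture
    statistics, Pearson-correlation feature screening, blockwise principal
    component reduction with Kaiser retention, and a cross-validated
    regression layer (multiple linear regression, partial least squares,
    support vector regression, back-propagation neural networks, random
    forests) topped by a stacking fusion model built on out-of-fold
    meta-features. A seeded synthetic leaf-image generator with ground-truth
    masks and latent nitrogen values makes the full pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    png,
    EBImage,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
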