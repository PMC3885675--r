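Package: psntexture
Title: Texture Analysis of Part-Solid Lung Nodules on CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and texture analysis of part-solid pulmonary
    nodules (PSNs) on thin-section CT. Generates synthetic CT-like nodule
    images with ground-glass and solid components calibrated to published
    group-level Hounsfield-unit statistics, rasterizes polygon contour
    annotations to pixel masks, computes first-order histogram texture
    features (moments, percentile CT numbers, attenuation ratio, sigmoid
    edge-fitting slope), and implements the discrimination pipeline for
    transient versus persistent PSNs: univariate screening, multivariate
    logistic regression with odds ratios, and comparison of correlated
    C-statistics by the DeLong method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
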