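Package: shearltex
Title: Shearlet-Domain Texture Descriptors for Histopathology Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds band-limited cone-adapted complex shearlet systems and
    decomposes 2-D images into directional sub-bands with magnitude and
    relative-phase coefficient stacks.  Computes four per-sub-band texture
    descriptor families (co-occurrence/Haralick statistics, rotation-invariant
    uniform local binary patterns, local oriented statistics information
    booster, and segmentation-based fractal texture analysis), fuses them into
    combined feature spaces, reduces dimensionality with varimax-rotated
    principal components, and evaluates support vector machine and bagged
    decision tree classifiers under stratified k-fold cross-validation with
    accuracy, AUC, sensitivity and precision reporting.  Includes a
    deterministic generator of oriented synthetic textures for end-to-end
    testing, baseline shearlet-domain descriptor sets from the texture
    classification literature, and a folder-per-class image corpus loader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    pROC,
    randomForest,
    png,
    tiff,
    stats,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
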