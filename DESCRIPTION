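Package: fundushr
Title: Five-Stage Hypertensive Retinopathy Grading from Color Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for grading hypertensive retinopathy
    (grades 0-4) from color retinal photographs. Provides perceptual
    enhancement of fundus images in the CIECAM02 JCh appearance space
    (adaptive gamma correction of the lightness plane, luminance-gain
    relighting and a blur-subtraction contrast boost), pixel-level lesion
    labelling by a shallow convolutional feature extractor feeding a random
    forest, instance separation of touching lesions via an encoder-decoder
    mask network followed by Otsu thresholding, morphology, distance
    transform and marker-controlled watershed, a dense-block grading
    classifier trained with a Kullback-Leibler divergence loss, and a
    one-vs-rest evaluation suite (sensitivity, specificity, precision, F1,
    MCC, AUC) with stratified k-fold cross-validation. A seeded synthetic
    fundus phantom generator with grade-dependent lesions and per-pixel
    masks makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
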