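Package: polarcnn
Title: Ischemia Classification from Stress-Perfusion Polar Maps with a Compact 2D CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying myocardial ischemia from
    stress myocardial blood flow (MBF) polar-map images. Provides a synthetic
    generator of labelled bullseye polar maps (segmental MBF over coronary
    territories, rainbow colormap over a fixed display scale), image loading
    and preprocessing (crop, resize, [0,1] scaling), a compact four-layer 2D
    convolutional neural network trained with class-weighted binary
    cross-entropy, a repeated-training stability protocol with majority-vote
    category assignment, a quantitative clinical-threshold comparator
    (stress MBF < 2.3 ml/g/min), and the full evaluation stack: confusion
    metrics, two-point ROC AUC, decision-curve net benefit and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
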