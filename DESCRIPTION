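Package: seiznet
Title: Seizure Detection from 2D Representations of EEG with Scalable
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modular pipeline for automatic seizure detection from
    electroencephalogram (EEG) recordings. Records are decomposed with an
    overlapping sliding time window, each windowed slice is converted to a
    two-dimensional feature map (a continuous wavelet transform scalogram
    for single-channel EEG, or a channel-by-frequency Fourier magnitude
    matrix for multichannel EEG), rendered as a three-channel image, and
    classified with a compound-scalable mobile-inverted-bottleneck
    convolutional network whose depth, width and input resolution scale
    jointly. Includes readers for single-channel ASCII EEG clips and
    multichannel EDF recordings with plain-text seizure annotations, a
    seeded synthetic EEG generator for end-to-end testing, softmax/KNN/SVM
    classifier heads, sensitivity/specificity evaluation, and an
    experiment runner for pooled (intrapatient) and held-out-subject
    (interpatient) designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    class,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
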