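Package: thalscreen
Title: Automated Thalassaemia Screening from Haemoglobin Electrophoresis
    Strip Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated assessment of beta-thalassaemia trait
    from scanned haemoglobin electrophoresis strips. A multi-patient strip
    image is segmented into per-patient lane images by Gaussian filtering,
    image complementation, Otsu thresholding, two-scale morphological
    erosion with compensating dilation, and 8-connected component boundary
    detection; each lane is cropped and resampled to a fixed 30 x 150 RGB
    patch. Lane patches are classified as normal or thalassaemia by a small
    convolutional network trained under a stratified five-fold
    cross-validation protocol with seeded geometric augmentation (rotation,
    scaling, translation). Classifier performance is summarised with
    per-class and macro-averaged accuracy, recall, specificity, precision
    and F1 together with normal-approximation confidence half-widths, ROC
    curves with fold averaging, and per-image timing. Score-CAM saliency
    maps visualise which bands drive each decision. A seeded synthetic
    strip simulator with per-lane ground truth makes the whole pipeline
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
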