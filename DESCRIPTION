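Package: hsibrain
Title: Intraoperative Hyperspectral Brain-Tissue Classification with Snapshot Mosaic Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying brain tissue in intraoperative
    hyperspectral images from 25-band snapshot mosaic cameras. Provides a
    synthetic phantom-scene generator with known ground truth, the four-step
    pre-processing chain (cube creation from the 5x5 mosaic, white/dark
    reflectance calibration, spectral crosstalk correction, RMS
    normalization), spectral-angle-mapper ground-truth labeling, three
    supervised classifiers (linear SVM, random forest, and a patch-based 3D
    convolutional network), stratified double and triple 5-fold
    cross-validation for intra- and inter-patient experiments, and a full
    evaluation-metric suite including the band-normalized overall accuracy
    used to compare cameras with different spectral resolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    ranger,
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
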