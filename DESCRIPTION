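Package: greyunet
Title: Expanded U-Net Segmentation and Recognition of Breast Ultrasound
    Images with Grey-Level Probability Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation and three-class recognition (normal tissue,
    benign tumour, malignant tumour) of breast ultrasound images with an
    expanded U-Net: ordinary class masks are re-encoded as grey-level
    probability labels (0, 0.5, 1 on three channels), the network is trained
    with a ternary (expanded) cross-entropy loss, and greyscale output maps
    are scored with grey-mass Dice and IOU coefficients that compare total
    grey value inside per-class grey bands rather than binary overlap.
    Includes a dropout-regularized U-Net built on a small vectorized CNN
    engine, a synthetic speckle-phantom generator with benign and malignant
    lesion morphologies plus geometric augmentation, and a train / predict /
    evaluate pipeline with a command-line front end, so the whole method is
    exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
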