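Package: focalaug
Title: Region-Targeted Augmentation and Evaluation for Detection Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bounding-box-targeted ("focused") data augmentation of
    object-detection datasets, built for CT rib-fracture detection workflows.
    Applies multiplicative speckle noise followed by Gaussian smoothing only
    inside annotated fracture regions, alongside a conventional whole-image
    augmentation baseline (random rotation, brightness/contrast, blur) with
    correct bounding-box geometry. Includes a complete detector-evaluation
    engine (IoU matching, precision/recall, 101-point interpolated average
    precision, mAP@50 and mAP@50-95, F1-confidence curves, comparison tables)
    and a synthetic CT-like phantom generator with a simulated detector, so
    the whole pipeline is testable without clinical data. Datasets use the
    normalized "class cx cy w h" label format with a YAML manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
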