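Package: mhseg
Title: Macular Hole Segmentation in Retinal OCT B-Scans by Multilevel
    Thresholding and Derivative Edge Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and segments full-thickness macular holes in single
    optical coherence tomography (OCT) B-scans. The pipeline combines
    local-statistics adaptive speckle denoising, Sobel derivative edge
    detection with an erf blurred-step edge-profile model, exhaustive
    multilevel Otsu (and histogram-valley) thresholding, and foveal-
    depression-focused hole candidate extraction, followed by hole shape
    feature computation and pixel-wise evaluation metrics (accuracy,
    sensitivity, Jaccard index, Dice). A synthetic fovea-centered B-scan
    phantom generator with ground-truth masks makes every stage testable
    without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
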