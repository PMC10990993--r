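Package: vtshape
Title: Semi-Automated Vocal-Tract Segmentation and Outlining from Real-Time MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage, scriptable pipeline for quantifying mid-sagittal
    vocal-tract shape from real-time MRI image sequences: variance-seeded
    region-of-interest definition with bimodal kernel-density thresholding for
    air/tissue classification, logfile-driven frame selection, per-pixel
    quality-assurance proportion maps with analyst exclusions, A*-bridged
    closed-contour outline extraction, and reproducible outline correction via
    declarative edit scripts. Includes intensity-inhomogeneity (bias field)
    pre-correction, validation metrics (Dice similarity, arc-length contour
    resampling, per-site inter-analyst disagreement profiles), and a synthetic
    dynamic phantom generator with exact ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
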