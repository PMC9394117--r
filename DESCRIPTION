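Package: clickseg
Title: Click-Guided Interactive Object Segmentation with Semantic Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for semantic-prior-guided interactive
    object segmentation of plant tissue images. Provides click-guidance
    encodings (minimum-distance and Gaussian maps), selection of a single
    semantic-prior channel from multi-channel class probability maps,
    simulated-user click sampling (initial budgeted sampling and iterative
    corrective sampling on connected error regions), pluggable segmentation
    backends with an iterative training scheme under a bootstrapped
    cross-entropy loss, the clicks-to-IoU evaluation protocol with
    mIoU-versus-clicks curves, and downstream tissue-trait statistics
    (per-class areas, relative areas and isolated-cluster counts) used for
    phenotyping. A synthetic multi-class instance scene generator makes the
    whole pipeline testable without external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
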