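Package: SRHdetect
Title: Patch-Based Residual CNN Tumor Detection for Stimulated Raman Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated intraoperative tumor detection on stimulated Raman
    histology (SRH) virtual slides. Forms digital H&E-like images from the two
    Raman channels (2845 and 2940 cm-1), extracts 300x300 pixel patches by a
    sliding window, classifies each patch into tumor / non-tumor / low quality
    with a compact pre-activation residual convolutional network trained under
    class-weighted categorical cross-entropy, aggregates patch probabilities
    into whole-slide predictions with low-quality exclusion, renders
    interpolated RGB probability heatmaps, and validates the pipeline with a
    full inter-rater reliability suite (two-way absolute-agreement ICC,
    Cohen's kappa, Cronbach's alpha, ROC-AUC with Hanley-McNeil intervals,
    Kendall's W). Includes a seeded synthetic SRH slide simulator so the whole
    workflow is testable without a microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
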