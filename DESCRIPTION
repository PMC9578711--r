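Package: flimMacro
Title: Macrophage Phenotyping from Two-Photon Fluorescence Lifetime Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive classification of macrophage polarisation
    (IFNg-M1 versus IL-4-M2) from two-photon fluorescence lifetime imaging
    (2P-FLIM) of NAD(P)H autofluorescence and FAD+ intensity. Provides a
    seeded simulator of TCSPC photon-decay image stacks under sequential
    metabolic-inhibitor treatments, bi-exponential lifetime fitting with a
    reduced chi-square gate, model-free phasor analysis, cell segmentation
    with per-cell feature aggregation, extracellular-flux (ECAR/OCR) rate
    metrics, and random-forests classification tuned by out-of-bag error
    with ROC-AUC, confusion counts and variable-importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    randomForest,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    pracma,
    uwot,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
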