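Package: icprofiler
Title: Immune-Checkpoint Profiling and Survival Stratification for Multiplex
    Immunofluorescence Tissue Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies immune markers and their colocalizations on
    immune-enriched tissue-microarray core images (tissue ROI with hole
    removal, per-channel intensity thresholding with size gates,
    DAPI-centered co-labeling, mean fluorescence intensity, core-size
    normalized log densities), assembles patient-level matrices with
    replicate-core averaging or per-core analysis, stratifies survival at
    mean +/- SEM cutoffs with ROC validation, ranks prognostic
    immune-checkpoint combinations (colocalization and additive modes,
    global scores, PCA coexpression groups, correlograms), and refines
    checkpoint-interacting proteins by evidence, redundancy, outcome and
    tissue criteria. Ships a synthetic tissue-microarray generator with
    ground-truth cell tables and planted survival effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    survival,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
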