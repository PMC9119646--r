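Package: piOmics
Title: Prediction-Interval Differential Analysis for Unreplicated
    Paired Multi-Omics Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential analysis of a single control/test sample pair
    across transcriptome, proteome and phosphoproteome. Implements
    prediction-interval (PI) based differential calling on a per-pair
    linear regression of log2 expression, CPM and column-mean
    normalization, peptide-evidence and reporter-ion CV filtering,
    phosphorylation-versus-abundance disambiguation against the global
    proteome, single-sample gene-set enrichment (ssGSEA) for subtype
    signatures, closed-form assay metrics (wound closure, invasion fold,
    cytokine ratios, delta-delta-Cq), and a synthetic paired-omics
    generator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Proteomics, DifferentialExpression,
    GeneSetEnrichment, Software
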