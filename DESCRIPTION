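Package: contrastSets
Title: Rank-Based Gene-Set Analysis of Differential-Expression Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for contrast-centred transcriptome analysis of factorial
    (age by treatment) count experiments: low-count filtering, trimmed-mean
    normalization, negative-binomial exact tests with Benjamini-Hochberg
    adjustment, signed inverse-p gene ranking, pre-ranked gene-set enrichment
    with a weighted Kolmogorov-Smirnov running sum and permutation null,
    per-sample rank-sum gene-set activation scores (Gsheat) with moderated-t
    differential set testing and enrichment-map export, two-dimensional
    multi-contrast set enrichment with quadrant classification and a
    miRNA-target mode, two-factor ANOVA reconstruction from published
    mean/SEM/n summaries, and a negative-binomial simulator with planted
    differential genes and activated sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    Matrix,
    SummarizedExperiment,
    S4Vectors,
    pheatmap,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    limma,
    edgeR,
    fgsea,
    car,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
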