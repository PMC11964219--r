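Package: scRankformer
Title: Rank-Value-Encoded Transformer Modelling of Single-Cell Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for building transcriptome foundation
    models from single-cell RNA-seq counts: per-dataset quality-control
    filters, corpus-wide nonzero gene medians, rank value encoding of cells
    into gene-token sentences, masked-token pretraining and [CLS]-head
    fine-tuning of a small transformer encoder, in silico gene deletion and
    activation with a cosine-similarity/Wilcoxon screening statistic, and
    deterministic one-to-one human-mouse ortholog resolution. Includes a
    negative-binomial corpus simulator with planted cell-type programs, QC
    artifacts and condition-specific causal genes so that every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    arrow
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Classification, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'tokenize.R'
    'io.R'
    'model.R'
    'ortholog.R'
    'perturb.R'
    'qc.R'
    'scRankformer-package.R'
    'synthetic.R'
    'train.R'
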