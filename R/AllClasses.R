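#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' RankCellDataset: raw single-cell counts with gene metadata
#'
#' A thin extension of [SingleCellExperiment::SingleCellExperiment] that
#' enforces the conventions the pipeline relies on: a `"counts"` assay of
#' non-negative integers oriented genes x cells, unique gene identifiers as
#' row names, and a logical `mito` column in `rowData()` flagging
#' mitochondrial genes. Per-cell metadata (dataset id, cell-type or
#' condition labels) lives in `colData()`.
#'
#' @export
setClass("RankCellDataset", contains = "SingleCellExperiment")

setValidity("RankCellDataset", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
        if (length(v) && (any(v < 0) || any(v != floor(v))))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "gene identifiers (rownames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (!"mito" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData column 'mito' (logical) is required")
    else if (!is.logical(SummarizedExperiment::rowData(object)$mito))
        msg <- c(msg, "rowData$mito must be logical")
    if (length(msg)) msg else TRUE
})

#' Simulation settings for the synthetic single-cell corpus
#'
#' Holds every knob of the negative-binomial corpus generator: matrix size,
#' cell-type gene programs (disjoint gene sets boosted by `programFold`),
#' per-gene baseline means, NB dispersion, the fraction of genes flagged
#' mitochondrial, and (for two-condition designs) the causal genes whose
#' expression separates the conditions by `causalFold`.
#'
#' @export
setClass("SyntheticConfig", representation(
    nCells = "integer", nGenes = "integer", nCellTypes = "integer",
    programSize = "integer", programFold = "numeric",
    baselineMean = "numeric", dispersion = "numeric",
    mitoFraction = "numeric", nConditions = "integer",
    causalGenes = "character", causalFold = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nCells < 0L || object@nGenes < 0L)
        msg <- c(msg, "nCells and nGenes must be non-negative")
    if (object@programSize * object@nCellTypes > object@nGenes)
        msg <- c(msg, "programSize * nCellTypes must not exceed nGenes (programs are disjoint)")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
    if (object@baselineMean <= 0) msg <- c(msg, "baselineMean must be > 0")
    if (object@mitoFraction < 0 || object@mitoFraction > 1)
        msg <- c(msg, "mitoFraction must lie in [0, 1]")
    if (!object@nConditions %in% c(1L, 2L))
        msg <- c(msg, "nConditions must be 1 or 2")
    if (length(msg)) msg else TRUE
})

#' Ground truth planted by the simulator
#'
#' Per-cell cell-type and condition labels, the exact QC filter(s) each
#' planted low-quality cell violates, and the causal gene set of a
#' two-condition design. Downstream tests compare pipeline output against
#' these records.
#'
#' @export
setClass("PlantedTruth", representation(
    cellType = "character", condition = "character",
    qcViolations = "list", causalGenes = "character"))

#' Thresholds for the four per-dataset cell filters
#'
#' The four exclusion rules applied per dataset: total counts beyond
#' `sdMultiplier` standard deviations of the dataset mean, mitochondrial
#' counts beyond the same band, fewer than `minGenesPerCell` detected genes,
#' and total counts strictly exceeding `maxTotalCounts`. `twoSided` selects
#' |x - mean| > k*sd (default) versus the upper tail only; `mitoMode`
#' selects summed mitochondrial counts (default) or the mitochondrial
#' fraction of the cell total.
#'
#' @export
setClass("QCThresholds", representation(
    sdMultiplier = "numeric", minGenesPerCell = "integer",
    maxTotalCounts = "numeric", twoSided = "logical", mitoMode = "character"),
    prototype(sdMultiplier = 3, minGenesPerCell = 7L,
              maxTotalCounts = 20000, twoSided = TRUE, mitoMode = "sum"))

setValidity("QCThresholds", function(object) {
    msg <- character()
    if (object@sdMultiplier <= 0 || object@minGenesPerCell <= 0L ||
        object@maxTotalCounts <= 0)
        msg <- c(msg, "all thresholds must be strictly positive")
    if (!object@mitoMode %in% c("sum", "fraction"))
        msg <- c(msg, "mitoMode must be 'sum' or 'fraction'")
    if (length(msg)) msg else TRUE
})

#' Pre-filter summary statistics of one dataset
#'
#' Mean and population standard deviation (divide by n) of per-cell total
#' counts and per-cell mitochondrial expression, computed over every cell of
#' a dataset before any removal.
#'
#' @export
setClass("QCStats", representation(
    meanTotal = "numeric", sdTotal = "numeric",
    meanMito = "numeric", sdMito = "numeric", nCells = "integer"))

#' Record of one quality-control filtering pass
#'
#' `keptIndex` holds the retained cell identifiers, `removed` one row per
#' excluded cell with the comma-joined names of every filter that fired,
#' and `countsPerFilter` the per-filter tally (a cell violating two filters
#' contributes to both).
#'
#' @export
setClass("FilterReport", representation(
    keptIndex = "character", removed = "DataFrame",
    countsPerFilter = "integer"))

#' Gene token vocabulary
#'
#' Maps gene identifiers to integer token ids. The special tokens occupy the
#' reserved low ids `[PAD] = 0`, `[MASK] = 1`, `[CLS] = 2`; gene tokens
#' follow in lexicographic order of gene identifier starting at 3.
#'
#' @export
setClass("GeneVocabulary", representation(genes = "character"))

setValidity("GeneVocabulary", function(object) {
    if (anyDuplicated(object@genes)) "gene identifiers must be unique"
    else if (is.unsorted(object@genes, strictly = TRUE) && length(object@genes) > 1)
        "genes must be stored in sorted (token) order"
    else TRUE
})

#' Tokenized corpus of cell sentences
#'
#' One integer token sequence per cell (leading `[CLS]`, genes in rank
#' order), per-cell metadata carried from the source dataset, and the hash
#' plus settings of the vocabulary/tokenizer that produced it so that
#' corpora and model checkpoints can be compatibility-checked.
#'
#' @export
setClass("TokenizedCorpus", representation(
    sentences = "list", cellData = "DataFrame",
    vocabHash = "character", tokenizer = "list"))

setValidity("TokenizedCorpus", function(object) {
    if (length(object@sentences) != nrow(object@cellData))
        "sentences and cellData must have matching length"
    else TRUE
})

#' Transformer encoder architecture settings
#'
#' The BERT-style encoder hyperparameters: positional capacity `maxInput`
#' (the sentence cap, `[CLS]` included), number of encoder blocks, attention
#' heads, embedding dimension, feed-forward expansion factor, SiLU
#' activation, dropout rate, vocabulary size and (optionally) the number of
#' classes of the `[CLS]` classification head (0 = no head).
#'
#' @export
setClass("EncoderConfig", representation(
    maxInput = "integer", nBlocks = "integer", nHeads = "integer",
    embedDim = "integer", ffMult = "integer", activation = "character",
    dropout = "numeric", vocabSize = "integer", nClasses = "integer",
    tieMLM = "logical"))

setValidity("EncoderConfig", function(object) {
    msg <- character()
    if (object@embedDim %% object@nHeads != 0L)
        msg <- c(msg, "embedDim must be divisible by nHeads")
    if (object@dropout < 0 || object@dropout >= 1)
        msg <- c(msg, "dropout must lie in [0, 1)")
    if (object@maxInput < 2L) msg <- c(msg, "maxInput must be >= 2")
    if (object@vocabSize < 4L)
        msg <- c(msg, "vocabSize must cover the 3 specials plus >= 1 gene")
    if (length(msg)) msg else TRUE
})

#' A trained (or freshly initialized) encoder with its heads
#'
#' Bundles the parameter list (embeddings, encoder blocks, masked-token head
#' and optional classification head), the [EncoderConfig] it instantiates,
#' and training provenance (seeds, schedules, loss traces).
#'
#' @export
setClass("ModelState", representation(
    params = "list", config = "EncoderConfig", provenance = "list"))

#' Optimization schedule for pretraining and fine-tuning
#'
#' AdamW with linear warmup to `maxLR` over `warmupSteps` followed by cosine
#' decay to zero, the defaults mirroring the published setup (pretraining:
#' 10 epochs, max learning rate 1e-3, 10,000 warmup steps, batch size 12,
#' weight decay 1e-3; fine-tuning: max learning rate 5e-5, 500 warmup
#' steps). `maskRate` is the masked-token fraction (0.15), `freezeBlocks`
#' the number of initial encoder blocks excluded from gradient updates, and
#' `maskMode` chooses the BERT 80/10/10 corruption split or pure masking.
#'
#' @export
setClass("TrainingSchedule", representation(
    epochs = "integer", maxLR = "numeric", warmupSteps = "integer",
    scheduler = "character", batchSize = "integer", optimizer = "character",
    weightDecay = "numeric", freezeBlocks = "integer", maskRate = "numeric",
    maskMode = "character", seed = "integer"))

setValidity("TrainingSchedule", function(object) {
    msg <- character()
    if (object@maskRate <= 0 || object@maskRate >= 1)
        msg <- c(msg, "maskRate must lie in (0, 1)")
    if (object@freezeBlocks < 0L) msg <- c(msg, "freezeBlocks must be >= 0")
    if (!object@scheduler %in% c("cosine", "linear"))
        msg <- c(msg, "scheduler must be 'cosine' or 'linear'")
    if (!object@maskMode %in% c("bert", "pure"))
        msg <- c(msg, "maskMode must be 'bert' or 'pure'")
    if (length(msg)) msg else TRUE
})

#' One-to-one human-mouse gene mapping with provenance
#'
#' The resolved forward map (human Ensembl id -> mouse Ensembl id), a
#' provenance table recording the chosen symbol, chosen MGI id and whether a
#' tie-break fired for each entry, and the identifier sets left unmapped in
#' either species.
#'
#' @export
setClass("OrthologTable", representation(
    forward = "character", provenance = "DataFrame",
    unmappedHuman = "character", unmappedMouse = "character"))

setValidity("OrthologTable", function(object) {
    msg <- character()
    if (anyDuplicated(names(object@forward)))
        msg <- c(msg, "forward map must be a function of human id")
    if (anyDuplicated(object@forward))
        msg <- c(msg, "forward map must be injective")
    if (any(names(object@forward) %in% object@unmappedHuman))
        msg <- c(msg, "an identifier cannot be both mapped and unmapped")
    if (length(msg)) msg else TRUE
})
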