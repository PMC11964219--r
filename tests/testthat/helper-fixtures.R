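# Shared fixtures. Everything is generated in code; the expensive trained
# models are built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

# small clean corpus with 3 cell-type programs
tinySim <- function() {
    if (is.null(.fixtures$tinySim))
        .fixtures$tinySim <- simulateCorpus(syntheticConfig(
            nCells = 300L, nGenes = 150L, nCellTypes = 3L,
            programSize = 10L, programFold = 8, baselineMean = 0.5,
            dispersion = 0.1, mitoFraction = 0.05, seed = 11L))
    .fixtures$tinySim
}

# tokenized version of tinySim plus its medians and vocabulary
tinyTokenized <- function() {
    if (is.null(.fixtures$tinyTok)) {
        sim <- tinySim()
        qc <- applyQCFilters(sim$dataset)
        med <- computeGeneMedians(qc$dataset)
        vocab <- buildVocabulary(rownames(qc$dataset), med)
        .fixtures$tinyTok <- list(
            dataset = qc$dataset, medians = med, vocab = vocab,
            corpus = encodeDataset(qc$dataset, med, vocab, maxInput = 128L))
    }
    .fixtures$tinyTok
}

# independent rank-value-encoding oracle: plain stable sort of
# (count/median, token id) pairs, written without reference to the
# tokenizer implementation
oracleEncode <- function(counts, medians, vocab, maxInput) {
    genes <- names(counts)[counts > 0]
    genes <- genes[genes %in% vocabGenes(vocab) & genes %in% names(medians)]
    if (!length(genes)) return(2L)
    score <- as.numeric(counts[genes]) / as.numeric(medians[genes])
    tok <- match(genes, vocabGenes(vocab)) + 2L
    df <- data.frame(tok = tok, score = score)
    df <- df[order(-df$score, df$tok), ]
    head(c(2L, df$tok), maxInput)
}

# brute-force per-gene rank of one gene inside one cell (1 = top)
bruteRank <- function(counts, medians, gene) {
    genes <- names(counts)[counts > 0]
    if (!(gene %in% genes)) return(NA_integer_)
    score <- as.numeric(counts[genes]) / as.numeric(medians[genes])
    ord <- genes[order(-score, genes)]
    match(gene, ord)
}

# the condition-pair corpus + trained tiny encoder used by the screening
# and fine-tuning gate tests; one pretraining + fine-tuning per test run
condPairModel <- function() {
    if (!is.null(.fixtures$condPair)) return(.fixtures$condPair)
    causal <- sprintf("ENSMUSG%011d", 41L)
    # a feature-selected panel of well-expressed genes (baseline mean 2):
    # with a single causal gene, fold 8 must be resolvable from one gene's
    # counts, which a 0.5-mean gene cannot provide at any model quality
    cfg <- syntheticConfig(nCells = 800L, nGenes = 200L, nCellTypes = 2L,
                           programSize = 20L, programFold = 8,
                           baselineMean = 2, dispersion = 0.1,
                           mitoFraction = 0.05, nConditions = 2L,
                           causalGenes = causal, causalFold = 8, seed = 13L)
    sim <- simulateConditionPair(cfg)
    qc <- applyQCFilters(sim$dataset)
    med <- computeGeneMedians(qc$dataset)
    vocab <- buildVocabulary(rownames(qc$dataset), med)
    corpus <- encodeDataset(qc$dataset, med, vocab, maxInput = 128L)
    enc <- tinyEncoderConfig(vocabSize(vocab), maxInput = 128L)
    model <- buildModel(enc, seed = 13L)
    pt <- pretrainModel(model, corpus,
                        pretrainSchedule(epochs = 3L, maxLR = 1e-3,
                                         warmupSteps = 30L, seed = 13L))
    ft <- finetuneModel(pt$model, corpus,
                        finetuneSchedule(epochs = 8L, maxLR = 3e-4,
                                         warmupSteps = 20L, seed = 13L),
                        labelColumn = "condition")
    .fixtures$condPair <- list(sim = sim, corpus = corpus, vocab = vocab,
                               medians = med, causal = causal,
                               model = ft$model, metrics = ft$metrics,
                               pretrained = pt$model)
    .fixtures$condPair
}
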