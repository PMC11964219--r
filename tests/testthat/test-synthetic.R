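test_that("generator is deterministic and honours edge cases", {
    cfg <- syntheticConfig(nCells = 40L, nGenes = 60L, nCellTypes = 2L,
                           programSize = 5L, seed = 1L)
    a <- simulateCorpus(cfg)
    b <- simulateCorpus(cfg)
    expect_identical(
        as.matrix(SummarizedExperiment::assay(a$dataset, "counts")),
        as.matrix(SummarizedExperiment::assay(b$dataset, "counts")))
    expect_identical(a$truth@cellType, b$truth@cellType)

    empty <- simulateCorpus(syntheticConfig(nCells = 0L, nGenes = 10L,
                                            nCellTypes = 1L,
                                            programSize = 2L, seed = 1L))
    expect_identical(dim(empty$dataset), c(10L, 0L))
    expect_length(empty$truth@cellType, 0L)
})

test_that("config invariants are enforced", {
    expect_error(syntheticConfig(nGenes = 30L, nCellTypes = 4L,
                                 programSize = 10L),
                 "programSize")
    expect_error(syntheticConfig(dispersion = 0), "dispersion")
    m <- SummarizedExperiment::assay(tinySim()$dataset, "counts")
    expect_true(all(m@x >= 0) && all(m@x == floor(m@x)))
})

test_that("program genes dominate the top ranks of their own cells", {
    # ranks computed by brute-force sort on the generated count matrix,
    # independent of the tokenizer under test
    sim <- simulateCorpus(syntheticConfig(
        nCells = 1000L, nGenes = 300L, nCellTypes = 4L, programSize = 20L,
        programFold = 8, baselineMean = 0.5, dispersion = 0.1, seed = 5L))
    counts <- as.matrix(SummarizedExperiment::assay(sim$dataset, "counts"))
    genes <- rownames(counts)
    programs <- lapply(1:4, function(t) genes[((t - 1) * 20 + 1):(t * 20)])
    hits <- vapply(seq_len(ncol(counts)), function(j) {
        x <- counts[, j]
        own <- programs[[as.integer(sub("type", "",
                                        sim$truth@cellType[j]))]]
        expressed <- genes[x > 0]
        top <- expressed[order(-x[expressed], expressed)][1:20]
        mean(top %in% own) > 0.5
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("counts match the negative-binomial moments", {
    # background genes of a single-type, single-program-free config
    cfg <- syntheticConfig(nCells = 2000L, nGenes = 100L, nCellTypes = 1L,
                           programSize = 0L, baselineMean = 0.8,
                           dispersion = 0.2, mitoFraction = 0, seed = 3L)
    sim <- simulateCorpus(cfg)
    x <- as.vector(as.matrix(
        SummarizedExperiment::assay(sim$dataset, "counts")))
    mu <- 0.8
    v <- mu + 0.2 * mu^2
    seMean <- sqrt(v / length(x))
    expect_lt(abs(mean(x) - mu), 3 * seMean)
    # variance within 3 SE of its sampling distribution (approximate SE)
    seVar <- sqrt(2 / (length(x) - 1)) * v
    expect_lt(abs(stats::var(x) - v), 4 * seVar)
})

test_that("condition pair plants causal genes with better ranks in B", {
    causal <- "ENSMUSG00000000061"
    cfg <- syntheticConfig(nCells = 400L, nGenes = 120L, nCellTypes = 2L,
                           programSize = 10L, nConditions = 2L,
                           causalGenes = causal, causalFold = 8, seed = 21L)
    sim <- simulateConditionPair(cfg)
    counts <- as.matrix(SummarizedExperiment::assay(sim$dataset, "counts"))
    med <- computeGeneMedians(sim$dataset)
    rk <- vapply(seq_len(ncol(counts)), function(j)
        as.numeric(bruteRank(counts[, j], med, causal)), numeric(1))
    cond <- sim$truth@condition
    expect_lt(mean(rk[cond == "B"], na.rm = TRUE),
              mean(rk[cond == "A"], na.rm = TRUE))
    # determinism of the pair
    sim2 <- simulateConditionPair(cfg)
    expect_identical(as.matrix(SummarizedExperiment::assay(sim2$dataset,
                                                           "counts")),
                     counts)
    # null case: fold 1 leaves conditions exchangeable in expectation
    cfg0 <- syntheticConfig(nCells = 400L, nGenes = 120L, nCellTypes = 2L,
                            programSize = 10L, nConditions = 2L,
                            causalGenes = causal, causalFold = 1,
                            seed = 21L)
    sim0 <- simulateConditionPair(cfg0)
    c0 <- as.matrix(SummarizedExperiment::assay(sim0$dataset, "counts"))
    tA <- colSums(c0)[sim0$truth@condition == "A"]
    tB <- colSums(c0)[sim0$truth@condition == "B"]
    expect_gt(stats::t.test(tA, tB)$p.value, 0.01)
    expect_error(simulateConditionPair(syntheticConfig(
        nCells = 10L, nGenes = 20L, nCellTypes = 1L, programSize = 0L,
        nConditions = 2L, causalGenes = "not_a_gene", causalFold = 2,
        seed = 1L)), "absent from the gene universe")
})

test_that("planted QC violations trip exactly the intended filters", {
    sim <- tinySim()
    planted <- plantQCViolations(
        sim$dataset,
        violations = c(min_genes = 3L, max_total = 2L, sd_total = 2L,
                       sd_mito = 2L),
        seed = 2L)
    viol <- planted$truth@qcViolations
    badNames <- grep("^bad_", names(viol), value = TRUE)
    expect_length(badNames, 9L)
    minG <- grep("min_genes", badNames, value = TRUE)
    expect_length(minG, 3L)
    counts <- SummarizedExperiment::assay(planted$dataset, "counts")
    expect_true(all(Matrix::colSums(counts[, minG] > 0) <= 6))
    maxT <- grep("max_total", badNames, value = TRUE)
    expect_length(maxT, 2L)
    expect_true(all(Matrix::colSums(counts[, maxT]) > 20000))
    for (nm in badNames) {
        want <- sub("^bad_([a-z_]+)_\\d+$", "\\1", nm)
        expect_true(want %in% viol[[nm]])
    }
    # all-zero spec leaves the dataset untouched
    same <- plantQCViolations(sim$dataset, violations = c(min_genes = 0L))
    expect_identical(dim(same$dataset), dim(sim$dataset))
    expect_length(same$truth@qcViolations, 0L)
})
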