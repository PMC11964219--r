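.pvocab <- function(n = 10L) {
    genes <- sprintf("g%02d", seq_len(n))
    buildVocabulary(genes, stats::setNames(rep(1, n), genes))
}

test_that("deletion removes the token and shifts later ranks forward", {
    v <- .pvocab()
    s <- c(2L, 3L, 4L, 5L, 6L)
    d <- deleteGene(s, geneOf(v, 4L), v)
    expect_identical(as.integer(d), c(2L, 3L, 5L, 6L))
    expect_true(attr(d, "perturbed"))
    d2 <- deleteGene(s, geneOf(v, 12L), v)
    expect_identical(as.integer(d2), s)
    expect_false(attr(d2, "perturbed"))
    expect_error(deleteGene(s, "nope", v), "absent from vocabulary")
})

test_that("activation moves the gene to rank 1", {
    v <- .pvocab()
    s <- c(2L, 3L, 4L, 5L)
    a <- activateGene(s, geneOf(v, 5L), v)
    expect_identical(as.integer(a), c(2L, 5L, 3L, 4L))
    # activating the rank-1 gene is a no-op
    expect_identical(as.integer(activateGene(s, geneOf(v, 3L), v)), s)
    # absent gene: inserted at rank 1; at capacity the last token drops
    full <- c(2L, 3L, 4L, 5L, 6L)
    a2 <- activateGene(full, geneOf(v, 9L), v, maxInput = 5L)
    expect_identical(as.integer(a2), c(2L, 9L, 3L, 4L, 5L))
    expect_true(attr(a2, "inserted"))
})

test_that("deleting after re-encoding equals zeroing the count", {
    fix <- tinyTokenized()
    counts <- as.matrix(SummarizedExperiment::assay(fix$dataset, "counts"))
    x <- counts[, 10]
    # untruncated encoding so truncation cannot mask the equivalence
    s <- encodeCell(x, fix$medians, fix$vocab, maxInput = 1000L)
    g <- geneOf(fix$vocab, s[5])
    x2 <- x
    x2[g] <- 0
    expect_identical(as.integer(deleteGene(s, g, fix$vocab)),
                     encodeCell(x2, fix$medians, fix$vocab,
                                maxInput = 1000L))
})

test_that("perturbation algebra holds exhaustively on short sentences", {
    v <- .pvocab(10L)
    toks <- 3:12
    set.seed(77)
    for (len in 0:6) {
        sentBodies <- if (len == 0) list(integer()) else
            c(lapply(1:20, function(i) sample(toks, len)),
              list(toks[seq_len(len)]))
        for (body in sentBodies) {
            s <- c(2L, body)
            for (tok in toks) {
                g <- geneOf(v, tok)
                d <- deleteGene(s, g, v)
                a <- activateGene(s, g, v, maxInput = 8L)
                present <- tok %in% body
                if (present) {
                    expect_length(d, length(s) - 1L)
                    expect_identical(as.integer(d),
                                     s[s != tok])
                    expect_length(a, length(s))
                } else {
                    expect_identical(as.integer(d), s)
                    expect_lte(length(a), 8L)
                }
                # activation is move-to-front, preserving other order
                expect_identical(as.integer(a)[2], tok)
                expect_identical(as.integer(a)[-2],
                                 utils::head(s[s != tok],
                                             length(a) - 1L))
                # idempotence of activation
                expect_identical(as.integer(activateGene(as.integer(a), g,
                                                         v, 8L)),
                                 as.integer(a))
                # delete after activate == delete (when present)
                if (present)
                    expect_identical(
                        as.integer(deleteGene(as.integer(a), g, v)),
                        as.integer(d))
            }
        }
    }
})

test_that("cosine similarity matches hand values and rejects zeros", {
    expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
    expect_equal(cosineSimilarity(c(1, 1), c(2, 2)), 1)
    expect_equal(cosineSimilarity(c(1, 2, 3), c(4, 5, 6)),
                 32 / sqrt(14 * 77), tolerance = 1e-10)
    expect_equal(round(cosineSimilarity(c(1, 2, 3), c(4, 5, 6)), 5),
                 0.97463)
    expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
    expect_error(cosineSimilarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("rank-sum test matches enumeration and the reference oracle", {
    r <- wilcoxonRankSum(c(1, 2), c(3, 4))
    expect_identical(r$method, "exact")
    expect_equal(r$p, 2 / 6, tolerance = 1e-12)
    same <- wilcoxonRankSum(1:5 + 0.5, 1:5 + 0.5)
    expect_gte(same$p, 0.99)
    expect_error(wilcoxonRankSum(numeric(), 1:3), "non-empty")
    # exhaustive tie-free sweep against stats::wilcox.test (exact mode)
    set.seed(10)
    for (n in 1:5) for (m in 1:5) {
        if (n + m > 10) next
        for (rep in 1:3) {
            a <- sample(seq(0.1, 9.9, by = 0.1), n)
            b <- sample(setdiff(seq(0.1, 9.9, by = 0.1), a), m)
            mine <- wilcoxonRankSum(a, b)
            ref <- stats::wilcox.test(a, b, exact = TRUE)
            expect_equal(mine$U, unname(ref$statistic), tolerance = 1e-12)
            expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
        }
    }
    # large-sample normal path agrees closely with the reference
    set.seed(11)
    a <- stats::rnorm(40); b <- stats::rnorm(45, 0.3)
    mine <- wilcoxonRankSum(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_identical(mine$method, "normal")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
})

test_that("perturbation reports are assembled and reproducible", {
    fix <- condPairModel()
    cond <- as.character(cellData(fix$corpus)$condition)
    start <- sentences(fix$corpus)[cond == "B"][1:25]
    goal <- sentences(fix$corpus)[cond == "A"][1:40]
    r1 <- perturbationTest(fix$model, fix$causal, "delete", start, goal,
                           fix$vocab, nRandom = 2L, seed = 4L)
    r2 <- perturbationTest(fix$model, fix$causal, "delete", start, goal,
                           fix$vocab, nRandom = 2L, seed = 4L)
    expect_identical(as.data.frame(r1), as.data.frame(r2))
    expect_true(r1$p_value >= 0 && r1$p_value <= 1)
    expect_identical(r1$significant, r1$p_value < 0.05)
    expect_true(abs(r1$mean_specific) <= 1 && abs(r1$mean_random) <= 1)
    expect_error(perturbationTest(fix$model, fix$causal, "delete",
                                  list(), goal, fix$vocab),
                 "non-empty")
    # deleting a gene absent from every start cell is an error
    g <- vocabGenes(fix$vocab)[10]
    tok <- tokenId(fix$vocab, g)
    startWithout <- lapply(start, function(s) s[s != tok])
    expect_error(perturbationTest(fix$model, g, "delete", startWithout,
                                  goal, fix$vocab),
                 "nothing to perturb")
})

test_that("screening ranks genes stably and applies the accuracy gate", {
    fix <- condPairModel()
    cond <- as.character(cellData(fix$corpus)$condition)
    start <- sentences(fix$corpus)[cond == "B"][1:20]
    goal <- sentences(fix$corpus)[cond == "A"][1:30]
    cands <- c(fix$causal,
               setdiff(vocabGenes(fix$vocab), fix$causal)[c(5, 50, 90)])
    t1 <- screenGenes(fix$model, start, goal, cands, op = "delete",
                      vocab = fix$vocab, nRandom = 2L, seed = 9L)
    t2 <- screenGenes(fix$model, start, goal, rev(cands), op = "delete",
                      vocab = fix$vocab, nRandom = 2L, seed = 9L)
    expect_identical(as.data.frame(t1), as.data.frame(t2))
    expect_true(all(diff(t1$shift) <= 1e-12))
    expect_true(all(t1$q_value >= t1$p_value - 1e-12, na.rm = TRUE))
    expect_error(screenGenes(fix$model, start, list(), cands,
                             vocab = fix$vocab), "goal")
    expect_error(screenGenes(fix$model, start, goal, cands,
                             vocab = fix$vocab, accuracy = 0.5),
                 "below the 0.90 gate")
    expect_silent(screenGenes(fix$model, start, goal, cands[1],
                              vocab = fix$vocab, accuracy = 0.5,
                              overrideGate = TRUE, nRandom = 1L,
                              seed = 1L))
})
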