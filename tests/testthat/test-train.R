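test_that("token masking targets the right count and never the specials", {
    s <- c(2L, seq(3L, by = 1L, length.out = 100L))
    mk <- maskTokens(s, maskRate = 0.15, vocabSize = 200L, seed = 1L)
    expect_length(mk$positions, 15L)               # floor(0.15 * 100)
    expect_false(1L %in% mk$positions)             # [CLS] position
    expect_identical(mk$targets, s[mk$positions])
    # min-1 rule on a single-gene sentence
    mk1 <- maskTokens(c(2L, 9L), maskRate = 0.15, vocabSize = 20L,
                      seed = 2L)
    expect_length(mk1$positions, 1L)
    # [CLS] never selected over many seeded draws; corrupted tokens are
    # [MASK] or gene tokens, never [PAD]/[CLS]
    for (sd in 1:1000) {
        mk <- maskTokens(s, 0.15, vocabSize = 200L, seed = sd)
        expect_false(any(mk$positions == 1L))
        expect_true(all(mk$tokens[mk$positions] != 0L &
                        mk$tokens[mk$positions] != 2L))
    }
    expect_error(maskTokens(s, 1.5, 200L), "maskRate")
    # pure mode replaces every target with [MASK]
    mkp <- maskTokens(s, 0.15, 200L, seed = 3L, maskMode = "pure")
    expect_true(all(mkp$tokens[mkp$positions] == 1L))
})

test_that("empirical mask fraction tracks the configured rate", {
    s <- c(2L, seq(3L, by = 1L, length.out = 120L))
    fr <- vapply(1:1000, function(sd)
        length(maskTokens(s, 0.15, 300L, seed = sd)$positions) / 120,
        numeric(1))
    expect_lt(abs(mean(fr) - 0.15), 0.01)
})

test_that("the schedule warms up linearly and decays to zero", {
    sch <- trainingSchedule(maxLR = 1e-3, warmupSteps = 100L)
    expect_identical(learningRate(0, sch, 1000), 0)
    expect_identical(learningRate(100, sch, 1000), 1e-3)
    expect_equal(learningRate(50, sch, 1000), 5e-4)
    expect_equal(learningRate(1000, sch, 1000), 0)
    lrs <- vapply(100:1000, learningRate, numeric(1), schedule = sch,
                  totalSteps = 1000)
    expect_true(all(diff(lrs) <= 1e-12))   # monotone non-increasing
    # cosine midpoint
    expect_equal(learningRate(550, sch, 1000), 1e-3 * 0.5)
})

test_that("classifier metrics match hand computation", {
    m <- evaluateClassifier(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
    expect_equal(m$accuracy, 0.75)
    expect_equal(m$perClass$f1[m$perClass$class == "A"], 2 / 3)
    expect_equal(m$perClass$f1[m$perClass$class == "B"], 4 / 5)
    expect_equal(m$macroF1, (2 / 3 + 4 / 5) / 2, tolerance = 1e-10)
    perfect <- evaluateClassifier(c("x", "y"), c("x", "y"))
    expect_identical(perfect$accuracy, 1)
    expect_identical(perfect$macroF1, 1)
    expect_identical(evaluateClassifier(c("a", "a"), c("a", "a"))$accuracy, 1)
    expect_error(evaluateClassifier(c("a"), c("b")), "disjoint")
    expect_error(evaluateClassifier(c("a"), c("a", "b")), "equal length")
})

test_that("stratified splits are disjoint, exhaustive and reproducible", {
    labels <- rep(c("A", "B", "C"), times = c(40, 25, 10))
    s1 <- stratifiedSplit(labels, 0.8, seed = 5L)
    s2 <- stratifiedSplit(labels, 0.8, seed = 5L)
    expect_identical(s1, s2)
    expect_length(intersect(s1$train, s1$test), 0L)
    expect_setequal(c(s1$train, s1$test), seq_along(labels))
    expect_identical(sum(labels[s1$train] == "A"), 32L)
    expect_identical(sum(labels[s1$train] == "B"), 20L)
    expect_identical(sum(labels[s1$train] == "C"), 8L)
    expect_true(all(c("A", "B", "C") %in% labels[s1$test]))
})

test_that("pretraining reduces the masked-token loss deterministically", {
    fix <- tinyTokenized()
    cfg <- tinyEncoderConfig(vocabSize(fix$vocab), maxInput = 128L)
    m <- buildModel(cfg, seed = 1L)
    sch <- pretrainSchedule(epochs = 3L, maxLR = 1e-3, warmupSteps = 10L,
                            seed = 1L)
    sub <- methods::new("TokenizedCorpus",
                        sentences = sentences(fix$corpus)[1:96],
                        cellData = cellData(fix$corpus)[1:96, ],
                        vocabHash = fix$corpus@vocabHash,
                        tokenizer = fix$corpus@tokenizer)
    r1 <- pretrainModel(m, sub, sch)
    expect_lt(r1$lossTrace[3], r1$lossTrace[1])
    r2 <- pretrainModel(m, sub, sch)
    expect_equal(r1$lossTrace, r2$lossTrace, tolerance = 1e-4)
    expect_error(pretrainModel(m, methods::new("TokenizedCorpus",
        sentences = list(), cellData = S4Vectors::DataFrame(),
        vocabHash = "x", tokenizer = list()), sch), "empty")
})

test_that("trained masked-token accuracy beats the frequency baseline", {
    fix <- condPairModel()
    model <- fix$pretrained
    corpus <- fix$corpus
    sents <- sentences(corpus)[seq(1, 301, by = 10)]
    # frequency-matching baseline: always predict the commonest gene token
    freqs <- table(unlist(sentences(corpus)))
    freqs <- freqs[names(freqs) != "2"]
    baseline <- max(freqs) / sum(freqs)
    hits <- 0L; tot <- 0L
    for (i in seq_along(sents)) {
        mk <- maskTokens(sents[[i]], 0.15, model@config@vocabSize,
                         seed = i, maskMode = "pure")
        pr <- predictMasked(model, mk$tokens)[[1]]
        pred <- max.col(pr) - 1L
        hits <- hits + sum(pred == mk$targets)
        tot <- tot + length(mk$targets)
    }
    expect_gt(hits / tot, baseline)
})

test_that("freezing all blocks leaves encoder parameters bit-identical", {
    fix <- tinyTokenized()
    cfg <- tinyEncoderConfig(vocabSize(fix$vocab), maxInput = 128L)
    m <- buildModel(cfg, seed = 2L)
    sub <- methods::new("TokenizedCorpus",
                        sentences = sentences(fix$corpus)[1:60],
                        cellData = cellData(fix$corpus)[1:60, ],
                        vocabHash = fix$corpus@vocabHash,
                        tokenizer = fix$corpus@tokenizer)
    sch <- finetuneSchedule(epochs = 2L, maxLR = 1e-3, warmupSteps = 5L,
                            freezeBlocks = 2L, seed = 3L)
    r <- finetuneModel(m, sub, sch, labelColumn = "cell_type")
    expect_identical(r$model@params$blocks, m@params$blocks)
    # embeddings and head still moved
    expect_false(identical(r$model@params$tokEmb, m@params$tokEmb))
})

test_that("fine-tuning recovers well-separated planted cell types", {
    fix <- tinyTokenized()
    cfg <- tinyEncoderConfig(vocabSize(fix$vocab), maxInput = 128L)
    m <- buildModel(cfg, seed = 5L)
    pt <- pretrainModel(m, fix$corpus,
                        pretrainSchedule(epochs = 2L, maxLR = 1e-3,
                                         warmupSteps = 20L, seed = 5L))
    sch <- finetuneSchedule(epochs = 6L, maxLR = 5e-4, warmupSteps = 10L,
                            seed = 5L)
    r <- finetuneModel(pt$model, fix$corpus, sch, labelColumn = "cell_type")
    expect_gte(r$metrics$accuracy, 0.9)
    expect_length(intersect(r$metrics$split$train, r$metrics$split$test), 0L)
    expect_identical(nrow(r$history), 6L)
})

test_that("zero-shot nearest-centroid classification behaves", {
    ref <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 1, 0))
    lab <- c("x", "y", "x", "y")
    # query equal to a centroid, and on one axis of orthogonal centroids
    r <- zeroShotClassify(rbind(c(1, 0, 0), c(0, 2, 0)), ref, lab)
    expect_identical(r$labels, c("x", "y"))
    expect_error(zeroShotClassify(matrix(1, 1, 3),
                                  matrix(numeric(), 0, 3), character()),
                 "empty")
    # trained embeddings separate planted types above chance
    fix <- condPairModel()
    lab2 <- as.character(cellData(fix$corpus)$cell_type)
    emb <- embedCells(fix$pretrained, sentences(fix$corpus)[1:160])
    zs <- zeroShotClassify(emb[81:160, ], emb[1:80, ], lab2[1:80],
                           truth = lab2[81:160])
    expect_gt(zs$metrics$accuracy, 1 / length(unique(lab2)))
})
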