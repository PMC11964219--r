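test_that("model construction honours the published architecture", {
    cfg <- encoderConfig(vocabSize = 100L)
    expect_identical(cfg@maxInput, 2048L)
    expect_identical(cfg@nBlocks, 6L)
    expect_identical(cfg@nHeads, 4L)
    expect_identical(cfg@embedDim, 256L)
    expect_identical(cfg@dropout, 0.02)
    m <- buildModel(cfg, seed = 2L)
    expect_length(m@params$blocks, 6L)
    expect_identical(dim(m@params$blocks[[1]]$Wq), c(256L, 256L))
    expect_identical(dim(m@params$blocks[[1]]$W1), c(256L, 1024L))
    expect_identical(dim(m@params$tokEmb), c(100L, 256L))
    expect_identical(dim(m@params$posEmb), c(2048L, 256L))
    expect_error(encoderConfig(vocabSize = 100L, embedDim = 65L,
                               nHeads = 4L), "divisible")
})

test_that("identical seeds give identical initial outputs", {
    cfg <- tinyEncoderConfig(50L, maxInput = 32L)
    m1 <- buildModel(cfg, seed = 9L)
    m2 <- buildModel(cfg, seed = 9L)
    s <- list(c(2L, 5L, 9L, 4L))
    expect_identical(embedCells(m1, s), embedCells(m2, s))
})

test_that("masked-token distributions normalize and start near uniform", {
    cfg <- tinyEncoderConfig(60L, maxInput = 32L)
    m <- buildModel(cfg, seed = 1L)
    s <- c(2L, 7L, 1L, 12L, 1L, 30L)
    pr <- predictMasked(m, s)[[1]]
    expect_identical(nrow(pr), 2L)
    expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-5,
                 ignore_attr = TRUE)
    ent <- -rowSums(pr * log(pr))
    expect_lt(max(abs(ent - log(60))), 0.2)
    expect_error(predictMasked(m, c(2L, rep(5L, 40L))), "capacity")
})

test_that("embeddings are deterministic, well shaped and typed", {
    fix <- tinyTokenized()
    cfg <- tinyEncoderConfig(vocabSize(fix$vocab), maxInput = 128L)
    m <- buildModel(cfg, seed = 4L)
    ss <- sentences(fix$corpus)[1:6]
    e1 <- embedCells(m, ss)
    e2 <- embedCells(m, ss)
    expect_identical(e1, e2)            # dropout disabled at inference
    expect_identical(ncol(e1), 64L)
    expect_true(all(is.finite(e1)))
    expect_identical(attr(e1, "provenance")$pooling, "mean")
    # [CLS]-only sentence falls back to the [CLS] state with a warning
    expect_warning(eCls <- embedCells(m, list(c(2L))), "no gene tokens")
    expect_identical(ncol(eCls), 64L)
    expect_error(embedCells(m, ss, layer = 5L), "layer")
})

test_that("appending [PAD] never changes gene-token outputs", {
    cfg <- tinyEncoderConfig(50L, maxInput = 64L)
    m <- buildModel(cfg, seed = 6L)
    s <- c(2L, 10L, 20L, 30L)
    # same sentence alone and padded alongside a longer one
    e1 <- embedCells(m, list(s, c(2L, seq(3L, 45L, by = 2L))))
    e2 <- embedCells(m, list(s))
    expect_lt(max(abs(e1[1, ] - e2[1, ])), 1e-5)
})

test_that("permuting gene-token order changes the output", {
    cfg <- tinyEncoderConfig(50L, maxInput = 32L)
    m <- buildModel(cfg, seed = 8L)
    e <- embedCells(m, list(c(2L, 5L, 9L, 13L), c(2L, 13L, 9L, 5L)))
    expect_gt(max(abs(e[1, ] - e[2, ])), 1e-6)
})

test_that("classification head yields proper probabilities", {
    cfg <- tinyEncoderConfig(50L, maxInput = 32L, nClasses = 3L)
    m <- buildModel(cfg, seed = 2L)
    ss <- list(c(2L, 4L, 8L), c(2L, 30L, 7L, 12L))
    pr <- classifyCells(m, ss)
    expect_equal(unname(rowSums(pr)), c(1, 1), tolerance = 1e-5)
    # zero-weight head forces uniform probabilities
    m@params$clsW[] <- 0
    m@params$clsB[] <- 0
    pr0 <- classifyCells(m, ss)
    expect_equal(unname(pr0), matrix(1 / 3, 2, 3), tolerance = 1e-12)
    mNoHead <- buildModel(tinyEncoderConfig(50L, maxInput = 32L), seed = 1L)
    expect_error(classifyCells(mNoHead, ss), "no classification head")
})

test_that("checkpoints round-trip to identical outputs", {
    fix <- tinyTokenized()
    cfg <- tinyEncoderConfig(vocabSize(fix$vocab), maxInput = 128L,
                             nClasses = 2L)
    m <- buildModel(cfg, seed = 3L)
    d <- withr::local_tempdir()
    saveModel(m, d)
    m2 <- loadModel(d)
    ss <- sentences(fix$corpus)[1:4]
    expect_equal(embedCells(m, ss), embedCells(m2, ss), tolerance = 1e-6)
    expect_identical(m2@config@nClasses, 2L)
})

test_that("compiled kernels agree with the pure-R reference", {
    ns <- asNamespace("scRankformer")
    set.seed(31)
    cfg <- encoderConfig(vocabSize = 40L, maxInput = 24L, nBlocks = 2L,
                         nHeads = 2L, embedDim = 12L, ffMult = 2L,
                         dropout = 0)
    m <- buildModel(cfg, seed = 5L)
    sents <- list(c(2L, sample(3:39, 15)), c(2L, sample(3:39, 5)))
    Tm <- ns$.padBatch(sents, 24L)
    fC <- ns$.encodeBatch(m@params, cfg, Tm, train = TRUE)
    fR <- ns$.encodeBatchR(m@params, cfg, Tm, train = TRUE)
    expect_lt(max(abs(fC$H - fR$H)), 1e-10)
    dH <- matrix(stats::rnorm(nrow(fC$H) * 12), nrow(fC$H), 12)
    gC <- ns$.backwardBatch(m@params, cfg, fC, dH)
    gR <- ns$.backwardBatchR(m@params, cfg, fR, dH)
    expect_lt(max(abs(gC$tokEmb - gR$tokEmb)), 1e-10)
    expect_lt(max(abs(gC$blocks[[1]]$Wq - gR$blocks[[1]]$Wq)), 1e-10)
    expect_lt(max(abs(gC$blocks[[2]]$W2 - gR$blocks[[2]]$W2)), 1e-10)
    expect_lt(max(abs(gC$blocks[[2]]$ln2g - gR$blocks[[2]]$ln2g)), 1e-10)
})
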