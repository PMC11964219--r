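#' @include AllClasses.R AllGenerics.R
NULL

#' Encoder architecture constructors
#'
#' `encoderConfig()` defaults to the published architecture: positional
#' capacity 2048, 6 encoder blocks, 4 attention heads, embedding dimension
#' 256, SiLU activation, dropout 0.02. `tinyEncoderConfig()` is the
#' desk-scale preset (2 blocks, 2 heads, 64 dimensions, capacity 256) used
#' for CPU-sized experiments. The feed-forward inner dimension is
#' `ffMult * embedDim` (BERT convention).
#'
#' @param vocabSize total token count including the 3 specials
#' @param maxInput positional capacity (sentence cap, `[CLS]` included)
#' @param nBlocks,nHeads,embedDim,ffMult,dropout architecture knobs
#' @param nClasses size of the `[CLS]` classification head; 0 = no head
#' @param tieMLM tie the masked-token output projection to the input
#'   embeddings instead of learning an independent projection
#' @return an [EncoderConfig]
#' @export
encoderConfig <- function(vocabSize, maxInput = 2048L, nBlocks = 6L,
                          nHeads = 4L, embedDim = 256L, ffMult = 4L,
                          dropout = 0.02, nClasses = 0L, tieMLM = FALSE) {
    methods::new("EncoderConfig",
        maxInput = as.integer(maxInput), nBlocks = as.integer(nBlocks),
        nHeads = as.integer(nHeads), embedDim = as.integer(embedDim),
        ffMult = as.integer(ffMult), activation = "silu",
        dropout = as.numeric(dropout), vocabSize = as.integer(vocabSize),
        nClasses = as.integer(nClasses), tieMLM = isTRUE(tieMLM))
}

#' @rdname encoderConfig
#' @export
tinyEncoderConfig <- function(vocabSize, maxInput = 256L, nClasses = 0L,
                              dropout = 0.02) {
    encoderConfig(vocabSize, maxInput = maxInput, nBlocks = 2L, nHeads = 2L,
                  embedDim = 64L, ffMult = 4L, dropout = dropout,
                  nClasses = nClasses)
}

.initParams <- function(cfg, seed) {
    set.seed(seed)
    d <- cfg@embedDim; f <- cfg@ffMult * d; V <- cfg@vocabSize
    w <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    blocks <- lapply(seq_len(cfg@nBlocks), function(i) list(
        Wq = w(d, d), bq = numeric(d), Wk = w(d, d), bk = numeric(d),
        Wv = w(d, d), bv = numeric(d), Wo = w(d, d), bo = numeric(d),
        ln1g = rep(1, d), ln1b = numeric(d),
        W1 = w(d, f), b1 = numeric(f), W2 = w(f, d), b2 = numeric(d),
        ln2g = rep(1, d), ln2b = numeric(d)))
    p <- list(tokEmb = w(V, d), posEmb = w(cfg@maxInput, d),
              lnEmbG = rep(1, d), lnEmbB = numeric(d),
              blocks = blocks,
              mlmW = if (cfg@tieMLM) NULL else w(d, V), mlmB = numeric(V))
    if (cfg@nClasses > 0L) {
        p$clsW <- w(d, cfg@nClasses)
        p$clsB <- numeric(cfg@nClasses)
    }
    p
}

#' Initialize an encoder
#'
#' Randomly initializes all parameters (normal, sd 0.02; layer-norm gains 1,
#' biases 0) deterministically under `seed`.
#'
#' @param config an [EncoderConfig]
#' @param seed integer seed
#' @return a [ModelState]
#' @export
buildModel <- function(config, seed = 1L) {
    methods::validObject(config)
    methods::new("ModelState", params = .initParams(config, seed),
                 config = config,
                 provenance = list(initSeed = as.integer(seed),
                                   stages = list()))
}

# ---- forward / backward machinery --------------------------------------
# Hidden states are (B*L) x d matrices, sequence-major (sequence b occupies
# rows (b-1)*L + 1 .. b*L). PAD keys are masked with a large negative score
# so padded positions never influence real positions.

.layerNormF <- function(X, g, b, eps = 1e-5) {
    mu <- rowMeans(X)
    xc <- X - mu
    inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
    xhat <- xc * inv
    list(Y = xhat * rep(g, each = nrow(X)) + rep(b, each = nrow(X)),
         xhat = xhat, inv = inv)
}

.layerNormB <- function(dY, cache, g) {
    n <- nrow(dY)
    dXhat <- dY * rep(g, each = n)
    m1 <- rowMeans(dXhat)
    m2 <- rowMeans(dXhat * cache$xhat)
    list(dX = cache$inv * (dXhat - m1 - cache$xhat * m2),
         dG = colSums(dY * cache$xhat), dB = colSums(dY))
}

.silu <- function(z) { s <- 1 / (1 + exp(-z)); list(y = z * s, s = s) }
.siluGrad <- function(z, s) s * (1 + z * (1 - s))

.dropoutMask <- function(n, d, rate) {
    if (rate <= 0) return(NULL)
    matrix((stats::runif(n * d) >= rate) / (1 - rate), n, d)
}

.cfgList <- function(cfg) list(embedDim = cfg@embedDim, nHeads = cfg@nHeads,
                               nBlocks = cfg@nBlocks, dropout = cfg@dropout)

# one batch forward pass; Tm is B x L integer token matrix (PAD = 0).
# Dispatches to the compiled kernel; .encodeBatchR is the pure-R reference
# implementation kept for cross-checking.
.encodeBatch <- function(params, cfg, Tm, train = FALSE) {
    .cppEncode(params, .cfgList(cfg), Tm, train)
}

.backwardBatch <- function(params, cfg, fw, dH) {
    .cppBackward(params, .cfgList(cfg), fw, dH)
}

.encodeBatchR <- function(params, cfg, Tm, train = FALSE) {
    B <- nrow(Tm); L <- ncol(Tm); d <- cfg@embedDim
    H <- cfg@nHeads; dh <- d %/% H
    tvec <- as.vector(t(Tm))                  # sequence-major
    X <- params$tokEmb[tvec + 1L, , drop = FALSE] +
         params$posEmb[rep(seq_len(L), B), , drop = FALSE]
    lnE <- .layerNormF(X, params$lnEmbG, params$lnEmbB)
    X <- lnE$Y
    mEmb <- if (train) .dropoutMask(B * L, d, cfg@dropout)
    if (!is.null(mEmb)) X <- X * mEmb
    padCols <- lapply(seq_len(B), function(b) which(Tm[b, ] == .PAD))
    layers <- vector("list", cfg@nBlocks)
    caches <- if (train) vector("list", cfg@nBlocks)
    for (i in seq_len(cfg@nBlocks)) {
        blk <- params$blocks[[i]]
        Q <- X %*% blk$Wq + rep(blk$bq, each = B * L)
        K <- X %*% blk$Wk + rep(blk$bk, each = B * L)
        Vm <- X %*% blk$Wv + rep(blk$bv, each = B * L)
        Cc <- matrix(0, B * L, d)
        Ps <- if (train) vector("list", B)
        for (b in seq_len(B)) {
            rows <- ((b - 1L) * L + 1L):(b * L)
            pc <- padCols[[b]]
            if (train) Ps[[b]] <- vector("list", H)
            for (h in seq_len(H)) {
                hc <- ((h - 1L) * dh + 1L):(h * dh)
                S <- tcrossprod(Q[rows, hc, drop = FALSE],
                                K[rows, hc, drop = FALSE]) / sqrt(dh)
                if (length(pc)) S[, pc] <- -1e30
                S <- S - apply(S, 1L, max)
                E <- exp(S)
                P <- E / rowSums(E)
                Cc[rows, hc] <- P %*% Vm[rows, hc, drop = FALSE]
                if (train) Ps[[b]][[h]] <- P
            }
        }
        O <- Cc %*% blk$Wo + rep(blk$bo, each = B * L)
        mAttn <- if (train) .dropoutMask(B * L, d, cfg@dropout)
        if (!is.null(mAttn)) O <- O * mAttn
        ln1 <- .layerNormF(X + O, blk$ln1g, blk$ln1b)
        X1 <- ln1$Y
        Z1 <- X1 %*% blk$W1 + rep(blk$b1, each = B * L)
        act <- .silu(Z1)
        Fo <- act$y %*% blk$W2 + rep(blk$b2, each = B * L)
        mFF <- if (train) .dropoutMask(B * L, d, cfg@dropout)
        if (!is.null(mFF)) Fo <- Fo * mFF
        ln2 <- .layerNormF(X1 + Fo, blk$ln2g, blk$ln2b)
        layers[[i]] <- ln2$Y
        if (train)
            caches[[i]] <- list(Xin = X, Q = Q, K = K, V = Vm, Ps = Ps,
                                Cc = Cc, mAttn = mAttn, ln1 = ln1, X1 = X1,
                                Z1 = Z1, s = act$s, A1 = act$y, mFF = mFF,
                                ln2 = ln2)
        X <- ln2$Y
    }
    list(H = X, layers = layers, B = B, L = L, tvec = tvec,
         cache = if (train) list(lnE = lnE, mEmb = mEmb, blocks = caches,
                                 padCols = padCols))
}

# backward through the encoder given dH (gradient w.r.t. final hidden)
.backwardBatchR <- function(params, cfg, fw, dH) {
    B <- fw$B; L <- fw$L; d <- cfg@embedDim
    H <- cfg@nHeads; dh <- d %/% H
    n <- B * L
    cache <- fw$cache
    g <- .zeroGrads(params)
    dX <- dH
    for (i in rev(seq_len(cfg@nBlocks))) {
        blk <- params$blocks[[i]]
        cc <- cache$blocks[[i]]
        ln2b <- .layerNormB(dX, cc$ln2, blk$ln2g)
        g$blocks[[i]]$ln2g <- ln2b$dG; g$blocks[[i]]$ln2b <- ln2b$dB
        dRes2 <- ln2b$dX                    # grad w.r.t. X1 + F
        dF <- if (is.null(cc$mFF)) dRes2 else dRes2 * cc$mFF
        g$blocks[[i]]$W2 <- crossprod(cc$A1, dF)
        g$blocks[[i]]$b2 <- colSums(dF)
        dA1 <- tcrossprod(dF, blk$W2)
        dZ1 <- dA1 * .siluGrad(cc$Z1, cc$s)
        g$blocks[[i]]$W1 <- crossprod(cc$X1, dZ1)
        g$blocks[[i]]$b1 <- colSums(dZ1)
        dX1 <- dRes2 + tcrossprod(dZ1, blk$W1)
        ln1b <- .layerNormB(dX1, cc$ln1, blk$ln1g)
        g$blocks[[i]]$ln1g <- ln1b$dG; g$blocks[[i]]$ln1b <- ln1b$dB
        dRes1 <- ln1b$dX                    # grad w.r.t. X + O
        dO <- if (is.null(cc$mAttn)) dRes1 else dRes1 * cc$mAttn
        g$blocks[[i]]$Wo <- crossprod(cc$Cc, dO)
        g$blocks[[i]]$bo <- colSums(dO)
        dCc <- tcrossprod(dO, blk$Wo)
        dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
        for (b in seq_len(B)) {
            rows <- ((b - 1L) * L + 1L):(b * L)
            for (h in seq_len(H)) {
                hc <- ((h - 1L) * dh + 1L):(h * dh)
                P <- cc$Ps[[b]][[h]]
                dOh <- dCc[rows, hc, drop = FALSE]
                dP <- tcrossprod(dOh, cc$V[rows, hc, drop = FALSE])
                dV[rows, hc] <- crossprod(P, dOh)
                dS <- P * (dP - rowSums(dP * P))
                dQ[rows, hc] <- dS %*% cc$K[rows, hc, drop = FALSE] / sqrt(dh)
                dK[rows, hc] <- crossprod(dS, cc$Q[rows, hc, drop = FALSE]) /
                    sqrt(dh)
            }
        }
        Xin <- cc$Xin
        g$blocks[[i]]$Wq <- crossprod(Xin, dQ); g$blocks[[i]]$bq <- colSums(dQ)
        g$blocks[[i]]$Wk <- crossprod(Xin, dK); g$blocks[[i]]$bk <- colSums(dK)
        g$blocks[[i]]$Wv <- crossprod(Xin, dV); g$blocks[[i]]$bv <- colSums(dV)
        dX <- dRes1 + tcrossprod(dQ, blk$Wq) + tcrossprod(dK, blk$Wk) +
              tcrossprod(dV, blk$Wv)
    }
    if (!is.null(cache$mEmb)) dX <- dX * cache$mEmb
    lnEb <- .layerNormB(dX, cache$lnE, params$lnEmbG)
    g$lnEmbG <- lnEb$dG; g$lnEmbB <- lnEb$dB
    dEmb <- lnEb$dX
    tok <- fw$tvec + 1L
    acc <- rowsum(dEmb, group = tok, reorder = FALSE)
    g$tokEmb[as.integer(rownames(acc)), ] <-
        g$tokEmb[as.integer(rownames(acc)), ] + acc
    posIdx <- rep(seq_len(L), B)
    accP <- rowsum(dEmb, group = posIdx, reorder = FALSE)
    g$posEmb[as.integer(rownames(accP)), ] <-
        g$posEmb[as.integer(rownames(accP)), ] + accP
    g
}

.zeroGrads <- function(p) {
    rapply(p, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

# pad a list of token vectors into a B x L matrix
.padBatch <- function(sents, maxInput) {
    lens <- lengths(sents)
    if (any(lens > maxInput))
        stop("sentence longer than the model's positional capacity (",
             maxInput, ")")
    L <- max(lens)
    Tm <- matrix(.PAD, length(sents), L)
    for (b in seq_along(sents)) Tm[b, seq_len(lens[b])] <- sents[[b]]
    Tm
}

.softmaxRows <- function(Z) {
    mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
    E <- exp(Z - mx)
    E / rowSums(E)
}

.mlmWeights <- function(params, cfg) {
    if (cfg@tieMLM) t(params$tokEmb) else params$mlmW
}

#' Predict masked gene tokens
#'
#' Runs the encoder on sentences containing `[MASK]` tokens and returns,
#' for each sentence, the predicted probability distribution over the full
#' vocabulary at every masked position (rows sum to 1).
#'
#' @param model a [ModelState]
#' @param sentences a token vector or list of token vectors (each starting
#'   with `[CLS]`, length at most the model's `maxInput`)
#' @return a list (one element per sentence) of matrices
#'   `masked positions x vocabSize`, with the masked positions as rownames
#' @export
predictMasked <- function(model, sentences) {
    if (!is.list(sentences)) sentences <- list(sentences)
    cfg <- model@config
    Tm <- .padBatch(sentences, cfg@maxInput)
    fw <- .encodeBatch(model@params, cfg, Tm, train = FALSE)
    W <- .mlmWeights(model@params, cfg)
    L <- fw$L
    out <- vector("list", length(sentences))
    for (b in seq_along(sentences)) {
        pos <- which(sentences[[b]] == .MASK)
        if (!length(pos)) {
            out[[b]] <- matrix(numeric(), 0, cfg@vocabSize)
            next
        }
        rows <- (b - 1L) * L + pos
        logits <- fw$H[rows, , drop = FALSE] %*% W +
            rep(model@params$mlmB, each = length(rows))
        pr <- .softmaxRows(logits)
        rownames(pr) <- pos
        out[[b]] <- pr
    }
    out
}

#' Extract cell embeddings
#'
#' Pools the hidden states of one encoder layer into one vector per cell.
#' The default — mean over gene-token positions (excluding `[CLS]` and
#' `[PAD]`) at the final layer — is the pooling used for perturbation
#' similarity; `"cls"` pooling returns the `[CLS]` state instead. A
#' sentence containing only `[CLS]` falls back to the `[CLS]` state with a
#' warning. Dropout is disabled, so embeddings are deterministic.
#'
#' @param model a [ModelState]
#' @param sentences token vector or list thereof
#' @param layer encoder block whose output is pooled (1..nBlocks; default
#'   the final block)
#' @param pooling `"mean"` over gene tokens or `"cls"`
#' @param batchSize sentences per forward pass
#' @return matrix `cells x embedDim` with pooling provenance in
#'   `attr(, "provenance")`
#' @export
embedCells <- function(model, sentences, layer = model@config@nBlocks,
                       pooling = c("mean", "cls"), batchSize = 16L) {
    pooling <- match.arg(pooling)
    if (!is.list(sentences)) sentences <- list(sentences)
    cfg <- model@config
    if (layer < 1L || layer > cfg@nBlocks)
        stop("layer must lie in [1, ", cfg@nBlocks, "]")
    n <- length(sentences)
    out <- matrix(NA_real_, n, cfg@embedDim)
    idx <- split(seq_len(n), ceiling(seq_len(n) / batchSize))
    for (chunk in idx) {
        Tm <- .padBatch(sentences[chunk], cfg@maxInput)
        fw <- .encodeBatch(model@params, cfg, Tm, train = FALSE)
        Hl <- fw$layers[[layer]]
        L <- fw$L
        for (j in seq_along(chunk)) {
            s <- sentences[[chunk[j]]]
            genePos <- which(s != .CLS & s != .PAD)
            rows <- (j - 1L) * L + genePos
            if (pooling == "mean" && length(genePos)) {
                out[chunk[j], ] <- colMeans(Hl[rows, , drop = FALSE])
            } else {
                if (pooling == "mean")
                    warning("sentence with no gene tokens: returning the ",
                            "[CLS] state")
                out[chunk[j], ] <- Hl[(j - 1L) * L + 1L, ]
            }
        }
    }
    rownames(out) <- names(sentences)
    attr(out, "provenance") <- list(layer = as.integer(layer),
                                    pooling = pooling)
    out
}

#' Classify cells with the [CLS] head
#'
#' Runs the encoder and applies the classification head to the final-layer
#' `[CLS]` state, returning per-cell class probabilities (rows sum to 1).
#'
#' @inheritParams embedCells
#' @return matrix `cells x nClasses`; column names are the class labels
#'   stored at fine-tuning time (if any)
#' @export
classifyCells <- function(model, sentences, batchSize = 16L) {
    cfg <- model@config
    if (cfg@nClasses == 0L || is.null(model@params$clsW))
        stop("model has no classification head (nClasses = 0)")
    if (!is.list(sentences)) sentences <- list(sentences)
    n <- length(sentences)
    out <- matrix(NA_real_, n, cfg@nClasses)
    idx <- split(seq_len(n), ceiling(seq_len(n) / batchSize))
    for (chunk in idx) {
        Tm <- .padBatch(sentences[chunk], cfg@maxInput)
        fw <- .encodeBatch(model@params, cfg, Tm, train = FALSE)
        L <- fw$L
        rows <- (seq_along(chunk) - 1L) * L + 1L
        logits <- fw$H[rows, , drop = FALSE] %*% model@params$clsW +
            rep(model@params$clsB, each = length(chunk))
        out[chunk, ] <- .softmaxRows(logits)
    }
    colnames(out) <- model@provenance$classLabels
    rownames(out) <- names(sentences)
    out
}

#' Attach (or replace) a classification head
#'
#' @param model a [ModelState]
#' @param nClasses number of classes
#' @param seed seed for the head's initialization
#' @param labels optional class label names recorded in provenance
#' @return the model with a freshly initialized `[CLS]` head
#' @export
addClassificationHead <- function(model, nClasses, seed = 1L,
                                  labels = NULL) {
    cfg <- model@config
    cfg@nClasses <- as.integer(nClasses)
    set.seed(seed)
    model@config <- cfg
    model@params$clsW <- matrix(stats::rnorm(cfg@embedDim * nClasses,
                                             sd = 0.02),
                                cfg@embedDim, nClasses)
    model@params$clsB <- numeric(nClasses)
    if (!is.null(labels)) model@provenance$classLabels <- labels
    model
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `config.json` (architecture +
#' provenance) and `weights.rds` (the parameter list). Loading reproduces
#' identical outputs on identical inputs.
#'
#' @param model a [ModelState]
#' @param dir checkpoint directory
#' @export
saveModel <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- model@config
    jsonlite::write_json(list(
        maxInput = cfg@maxInput, nBlocks = cfg@nBlocks, nHeads = cfg@nHeads,
        embedDim = cfg@embedDim, ffMult = cfg@ffMult, dropout = cfg@dropout,
        vocabSize = cfg@vocabSize, nClasses = cfg@nClasses,
        tieMLM = cfg@tieMLM, provenance = model@provenance),
        file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
    saveRDS(model@params, file.path(dir, "weights.rds"))
    invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
    cj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
    cfg <- encoderConfig(cj$vocabSize, maxInput = cj$maxInput,
                         nBlocks = cj$nBlocks, nHeads = cj$nHeads,
                         embedDim = cj$embedDim, ffMult = cj$ffMult,
                         dropout = cj$dropout, nClasses = cj$nClasses,
                         tieMLM = cj$tieMLM)
    methods::new("ModelState", params = readRDS(file.path(dir, "weights.rds")),
                 config = cfg, provenance = as.list(cj$provenance))
}
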