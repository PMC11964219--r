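#' @include AllClasses.R AllGenerics.R model.R
NULL

#' Optimization schedules
#'
#' `trainingSchedule()` builds a [TrainingSchedule]; `pretrainSchedule()`
#' and `finetuneSchedule()` carry the published defaults (pretraining:
#' 10 epochs, max learning rate 1e-3, 10,000 warmup steps; fine-tuning:
#' max learning rate 5e-5, 500 warmup steps; both: cosine scheduler, AdamW,
#' batch size 12, weight decay 1e-3, 15% masked tokens). Desk-scale runs
#' pass smaller `epochs`/`warmupSteps`/`maxLR` explicitly.
#'
#' @param epochs,maxLR,warmupSteps,batchSize,weightDecay optimizer settings
#' @param scheduler `"cosine"` (default) or `"linear"` decay after warmup
#' @param freezeBlocks initial encoder blocks excluded from gradient updates
#' @param maskRate masked-token fraction for pretraining
#' @param maskMode `"bert"` (80/10/10 corruption) or `"pure"` (all `[MASK]`)
#' @param seed seed governing shuffling, masking and dropout
#' @export
trainingSchedule <- function(epochs = 10L, maxLR = 1e-3,
                             warmupSteps = 10000L, scheduler = "cosine",
                             batchSize = 12L, weightDecay = 1e-3,
                             freezeBlocks = 0L, maskRate = 0.15,
                             maskMode = "bert", seed = 1L) {
    methods::new("TrainingSchedule",
        epochs = as.integer(epochs), maxLR = as.numeric(maxLR),
        warmupSteps = as.integer(warmupSteps),
        scheduler = as.character(scheduler), batchSize = as.integer(batchSize),
        optimizer = "adamw", weightDecay = as.numeric(weightDecay),
        freezeBlocks = as.integer(freezeBlocks),
        maskRate = as.numeric(maskRate), maskMode = as.character(maskMode),
        seed = as.integer(seed))
}

#' @rdname trainingSchedule
#' @param ... overrides passed to `trainingSchedule()`
#' @export
pretrainSchedule <- function(...) {
    do.call(trainingSchedule,
            utils::modifyList(list(epochs = 10L, maxLR = 1e-3,
                                   warmupSteps = 10000L), list(...)))
}

#' @rdname trainingSchedule
#' @export
finetuneSchedule <- function(...) {
    do.call(trainingSchedule,
            utils::modifyList(list(epochs = 10L, maxLR = 5e-5,
                                   warmupSteps = 500L), list(...)))
}

#' Learning rate at a given step
#'
#' Linear warmup from 0 at step 0 to `maxLR` at step `warmupSteps`, then
#' cosine (or linear) decay to 0 at `totalSteps`.
#'
#' @param step step index (0-based)
#' @param schedule a [TrainingSchedule]
#' @param totalSteps total optimization steps of the run
#' @export
learningRate <- function(step, schedule, totalSteps) {
    w <- schedule@warmupSteps
    if (step <= w) {
        if (w == 0L) return(schedule@maxLR)
        return(schedule@maxLR * step / w)
    }
    if (step >= totalSteps) return(0)
    frac <- (step - w) / max(totalSteps - w, 1)
    if (schedule@scheduler == "cosine")
        schedule@maxLR * 0.5 * (1 + cos(pi * frac))
    else schedule@maxLR * (1 - frac)
}

#' Mask gene tokens of one sentence
#'
#' Selects `max(1, floor(maskRate * nGenes))` gene-token positions
#' uniformly without replacement — `[CLS]` and `[PAD]` are never
#' selectable — and corrupts them with the BERT 80/10/10 convention: 80%
#' become `[MASK]`, 10% a random gene token, 10% stay unchanged
#' (`maskMode = "pure"` masks all of them). Deterministic under `seed`.
#'
#' @param sentence integer token vector (leading `[CLS]`)
#' @param maskRate fraction of gene tokens to target, in (0, 1)
#' @param vocabSize total vocabulary size (needed for the random-token arm)
#' @param seed optional seed; if `NULL` the current RNG stream is used
#' @param maskMode `"bert"` or `"pure"`
#' @return list with `tokens` (corrupted sentence), `positions` (targeted
#'   positions) and `targets` (the true tokens at those positions)
#' @export
maskTokens <- function(sentence, maskRate = 0.15, vocabSize, seed = NULL,
                       maskMode = c("bert", "pure")) {
    maskMode <- match.arg(maskMode)
    if (maskRate <= 0 || maskRate >= 1)
        stop("maskRate must lie in (0, 1)")
    if (!length(sentence)) stop("sentence is empty")
    if (!is.null(seed)) set.seed(seed)
    genePos <- which(sentence >= .N_SPECIAL)
    if (!length(genePos))
        return(list(tokens = sentence, positions = integer(),
                    targets = integer()))
    nTar <- max(1L, floor(maskRate * length(genePos)))
    pos <- sort(genePos[sample.int(length(genePos), nTar)])
    out <- sentence
    targets <- sentence[pos]
    if (maskMode == "pure") {
        out[pos] <- .MASK
    } else {
        u <- stats::runif(nTar)
        out[pos[u < 0.8]] <- .MASK
        rnd <- u >= 0.8 & u < 0.9
        if (any(rnd))
            out[pos[rnd]] <- .N_SPECIAL - 1L + sample.int(
                vocabSize - .N_SPECIAL, sum(rnd), replace = TRUE)
    }
    list(tokens = out, positions = pos, targets = targets)
}

# ---- AdamW ------------------------------------------------------------

.adamInit <- function(params) {
    list(m = .zeroGrads(params), v = .zeroGrads(params), t = 0L)
}

# one AdamW step; weight decay applies to matrices (weights + embeddings),
# never to biases or layer-norm vectors; frozen leading encoder blocks are
# skipped entirely so their parameters stay bit-identical
.adamStep <- function(params, grads, state, lr, weightDecay,
                      freezeBlocks = 0L, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-6) {
    state$t <- state$t + 1L
    t <- state$t
    bc1 <- 1 - beta1^t
    bc2 <- 1 - beta2^t
    upd <- function(p, g, m, v) {
        if (is.null(p) || is.null(g)) return(list(p, m, v))
        if (is.list(p)) {
            for (k in seq_along(p)) {
                r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
                p[[k]] <- r[[1]]; m[[k]] <- r[[2]]; v[[k]] <- r[[3]]
            }
            return(list(p, m, v))
        }
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g * g
        step <- (m / bc1) / (sqrt(v / bc2) + eps)
        if (is.matrix(p)) step <- step + weightDecay * p
        list(p - lr * step, m, v)
    }
    for (nm in names(params)) {
        if (nm == "blocks") {
            for (i in seq_along(params$blocks)) {
                if (i <= freezeBlocks) next
                r <- upd(params$blocks[[i]], grads$blocks[[i]],
                         state$m$blocks[[i]], state$v$blocks[[i]])
                params$blocks[[i]] <- r[[1]]
                state$m$blocks[[i]] <- r[[2]]
                state$v$blocks[[i]] <- r[[3]]
            }
        } else {
            r <- upd(params[[nm]], grads[[nm]], state$m[[nm]],
                     state$v[[nm]])
            params[[nm]] <- r[[1]]
            state$m[[nm]] <- r[[2]]
            state$v[[nm]] <- r[[3]]
        }
    }
    list(params = params, state = state)
}

.checkCorpusFits <- function(corpus, cfg) {
    if (!length(sentences(corpus))) stop("corpus is empty")
    if (max(lengths(sentences(corpus))) > cfg@maxInput)
        stop("corpus sentences exceed the model's positional capacity")
}

# masked-LM loss + gradient w.r.t. final hidden for one batch
.mlmLossGrad <- function(params, cfg, fw, batchMasks) {
    L <- fw$L
    rows <- integer(); targets <- integer()
    for (b in seq_along(batchMasks)) {
        mk <- batchMasks[[b]]
        rows <- c(rows, (b - 1L) * L + mk$positions)
        targets <- c(targets, mk$targets)
    }
    if (!length(rows)) return(NULL)
    W <- .mlmWeights(params, cfg)
    Hm <- fw$H[rows, , drop = FALSE]
    logits <- Hm %*% W + rep(params$mlmB, each = length(rows))
    P <- .softmaxRows(logits)
    n <- length(rows)
    picked <- cbind(seq_len(n), targets + 1L)
    loss <- -mean(log(pmax(P[picked], 1e-12)))
    dLogits <- P
    dLogits[picked] <- dLogits[picked] - 1
    dLogits <- dLogits / n
    dH <- matrix(0, nrow(fw$H), cfg@embedDim)
    dH[rows, ] <- tcrossprod(dLogits, W)
    list(loss = loss, dH = dH,
         gW = crossprod(Hm, dLogits), gB = colSums(dLogits))
}

#' Masked-token pretraining
#'
#' Self-supervised pretraining: each epoch shuffles the corpus, masks 15%
#' (by default) of the gene tokens of every sentence, and minimizes
#' cross-entropy on the masked positions only, under AdamW with linear
#' warmup and cosine decay. The whole run is reproducible under the
#' schedule's seed.
#'
#' @param model a [ModelState]
#' @param corpus a non-empty [TokenizedCorpus]
#' @param schedule a [TrainingSchedule]
#' @param verbose print per-epoch losses
#' @return list with `model` (trained) and `lossTrace` (mean masked-token
#'   cross-entropy per epoch)
#' @export
pretrainModel <- function(model, corpus, schedule, verbose = FALSE) {
    cfg <- model@config
    .checkCorpusFits(corpus, cfg)
    sents <- sentences(corpus)
    n <- length(sents)
    params <- model@params
    stepsPerEpoch <- ceiling(n / schedule@batchSize)
    totalSteps <- schedule@epochs * stepsPerEpoch
    st <- .adamInit(params)
    set.seed(schedule@seed)
    lossTrace <- numeric(schedule@epochs)
    step <- 0L
    for (epoch in seq_len(schedule@epochs)) {
        perm <- sample.int(n)
        losses <- numeric(stepsPerEpoch)
        for (bi in seq_len(stepsPerEpoch)) {
            take <- perm[((bi - 1L) * schedule@batchSize + 1L):
                         min(bi * schedule@batchSize, n)]
            masks <- lapply(sents[take], maskTokens,
                            maskRate = schedule@maskRate,
                            vocabSize = cfg@vocabSize,
                            maskMode = schedule@maskMode)
            Tm <- .padBatch(lapply(masks, `[[`, "tokens"), cfg@maxInput)
            fw <- .encodeBatch(params, cfg, Tm, train = TRUE)
            lg <- .mlmLossGrad(params, cfg, fw, masks)
            if (is.null(lg)) next
            g <- .backwardBatch(params, cfg, fw, lg$dH)
            if (cfg@tieMLM) g$tokEmb <- g$tokEmb + t(lg$gW)
            else g$mlmW <- (g$mlmW %||% 0) + lg$gW
            g$mlmB <- (g$mlmB %||% 0) + lg$gB
            step <- step + 1L
            lr <- learningRate(step, schedule, totalSteps)
            r <- .adamStep(params, g, st, lr, schedule@weightDecay,
                           freezeBlocks = schedule@freezeBlocks)
            params <- r$params; st <- r$state
            losses[bi] <- lg$loss
        }
        lossTrace[epoch] <- mean(losses)
        if (verbose)
            message(sprintf("epoch %d/%d  masked-token loss %.4f",
                            epoch, schedule@epochs, lossTrace[epoch]))
    }
    model@params <- params
    model@provenance$stages$pretrain <- list(
        seed = schedule@seed, epochs = schedule@epochs,
        maxLR = schedule@maxLR, lossTrace = lossTrace)
    list(model = model, lossTrace = lossTrace)
}

#' Stratified train/test split
#'
#' Splits cell indices class by class so every class is represented in the
#' training set (and, when it has at least two members, in the test set).
#'
#' @param labels per-cell class labels
#' @param fraction training fraction, default 0.8
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
stratifiedSplit <- function(labels, fraction = 0.8, seed = 1L) {
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
    set.seed(seed)
    train <- integer()
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        nTr <- round(fraction * length(idx))
        nTr <- min(max(nTr, 1L), length(idx) - (length(idx) > 1L))
        train <- c(train, idx[sample.int(length(idx), nTr)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
}

#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1 and macro-F1 (the unweighted
#' mean of per-class F1 over the classes present in the truth). Undefined
#' precision or recall (empty denominator) counts as 0.
#'
#' @param predictions predicted labels
#' @param truth true labels
#' @return list with `accuracy`, `macroF1` and a `perClass` data frame
#' @export
evaluateClassifier <- function(predictions, truth) {
    if (length(predictions) != length(truth))
        stop("predictions and truth must have equal length")
    predictions <- as.character(predictions)
    truth <- as.character(truth)
    if (!length(intersect(predictions, truth)))
        stop("prediction and truth label sets are disjoint")
    classes <- sort(unique(truth))
    per <- do.call(rbind, lapply(classes, function(cl) {
        tp <- sum(predictions == cl & truth == cl)
        fp <- sum(predictions == cl & truth != cl)
        fn <- sum(predictions != cl & truth == cl)
        p <- if (tp + fp > 0) tp / (tp + fp) else 0
        r <- if (tp + fn > 0) tp / (tp + fn) else 0
        f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
        data.frame(class = cl, precision = p, recall = r, f1 = f1)
    }))
    list(accuracy = mean(predictions == truth),
         macroF1 = mean(per$f1), perClass = per)
}

#' Fine-tune the [CLS] classification head
#'
#' Adds (if absent) a classification head, freezes the first
#' `freezeBlocks` encoder blocks, trains on a stratified `splitFraction`
#' share of the cells and evaluates on the held-out rest after every epoch.
#' Per-epoch test metrics are recorded; the returned model and metrics
#' correspond to the best-accuracy epoch, flagged in `metrics$bestEpoch`.
#'
#' @param model a [ModelState] (pretrained or freshly initialized)
#' @param corpus a labeled [TokenizedCorpus]
#' @param schedule a [TrainingSchedule] (use [finetuneSchedule()])
#' @param splitFraction training fraction of the random split, default 0.8
#' @param labelColumn `cellData()` column holding the class labels
#' @param verbose print per-epoch accuracy
#' @return list with `model` (best-epoch weights), `metrics`
#'   (held-out metrics of the best epoch, plus `bestEpoch` and the `split`)
#'   and `history` (per-epoch test accuracy/macro-F1)
#' @export
finetuneModel <- function(model, corpus, schedule, splitFraction = 0.8,
                          labelColumn = "cell_type", verbose = FALSE) {
    cfg <- model@config
    .checkCorpusFits(corpus, cfg)
    labels <- cellData(corpus)[[labelColumn]]
    if (is.null(labels)) stop("no '", labelColumn, "' column in cellData")
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    y <- match(labels, classes)
    if (cfg@nClasses != length(classes) || is.null(model@params$clsW))
        model <- addClassificationHead(model, length(classes),
                                       seed = schedule@seed,
                                       labels = classes)
    cfg <- model@config
    split <- stratifiedSplit(labels, splitFraction, schedule@seed)
    if (!all(seq_along(classes) %in% y[split$train]))
        stop("a class is absent from the training split")
    sents <- sentences(corpus)
    params <- model@params
    nTr <- length(split$train)
    stepsPerEpoch <- ceiling(nTr / schedule@batchSize)
    totalSteps <- schedule@epochs * stepsPerEpoch
    st <- .adamInit(params)
    set.seed(schedule@seed)
    history <- data.frame(epoch = seq_len(schedule@epochs),
                          loss = NA_real_, accuracy = NA_real_,
                          macroF1 = NA_real_)
    best <- list(acc = -1, params = params, epoch = 0L)
    step <- 0L
    testSents <- sents[split$test]
    testY <- labels[split$test]
    for (epoch in seq_len(schedule@epochs)) {
        perm <- split$train[sample.int(nTr)]
        losses <- numeric(stepsPerEpoch)
        for (bi in seq_len(stepsPerEpoch)) {
            take <- perm[((bi - 1L) * schedule@batchSize + 1L):
                         min(bi * schedule@batchSize, nTr)]
            Tm <- .padBatch(sents[take], cfg@maxInput)
            fw <- .encodeBatch(params, cfg, Tm, train = TRUE)
            L <- fw$L
            rows <- (seq_along(take) - 1L) * L + 1L
            logits <- fw$H[rows, , drop = FALSE] %*% params$clsW +
                rep(params$clsB, each = length(take))
            P <- .softmaxRows(logits)
            picked <- cbind(seq_along(take), y[take])
            losses[bi] <- -mean(log(pmax(P[picked], 1e-12)))
            dLogits <- P
            dLogits[picked] <- dLogits[picked] - 1
            dLogits <- dLogits / length(take)
            dH <- matrix(0, nrow(fw$H), cfg@embedDim)
            dH[rows, ] <- tcrossprod(dLogits, params$clsW)
            g <- .backwardBatch(params, cfg, fw, dH)
            g$clsW <- (g$clsW %||% 0) +
                crossprod(fw$H[rows, , drop = FALSE], dLogits)
            g$clsB <- (g$clsB %||% 0) + colSums(dLogits)
            step <- step + 1L
            lr <- learningRate(step, schedule, totalSteps)
            r <- .adamStep(params, g, st, lr, schedule@weightDecay,
                           freezeBlocks = schedule@freezeBlocks)
            params <- r$params; st <- r$state
        }
        evalModel <- model; evalModel@params <- params
        pr <- classifyCells(evalModel, testSents)
        pred <- classes[max.col(pr, ties.method = "first")]
        m <- evaluateClassifier(pred, testY)
        history$loss[epoch] <- mean(losses)
        history$accuracy[epoch] <- m$accuracy
        history$macroF1[epoch] <- m$macroF1
        if (m$accuracy > best$acc)
            best <- list(acc = m$accuracy, params = params, epoch = epoch,
                         metrics = m)
        if (verbose)
            message(sprintf("epoch %d/%d  loss %.4f  test acc %.4f",
                            epoch, schedule@epochs, mean(losses),
                            m$accuracy))
    }
    model@params <- best$params
    model@provenance$classLabels <- classes
    model@provenance$stages$finetune <- list(
        seed = schedule@seed, epochs = schedule@epochs,
        freezeBlocks = schedule@freezeBlocks, bestEpoch = best$epoch,
        labelColumn = labelColumn, accuracy = best$acc)
    metrics <- best$metrics
    metrics$bestEpoch <- best$epoch
    metrics$split <- split
    list(model = model, metrics = metrics, history = history)
}

#' Zero-shot nearest-centroid classification
#'
#' Classifies cells without any fine-tuning: each query embedding is
#' assigned the class whose mean reference embedding it is most
#' cosine-similar to, ties broken by class name order.
#'
#' @param embeddings query matrix `cells x dim` (from [embedCells()])
#' @param reference labeled reference matrix `cells x dim`
#' @param refLabels per-row labels of `reference`
#' @param truth optional true labels of the queries; if given, metrics are
#'   computed with [evaluateClassifier()]
#' @return list with `labels`, the `similarity` matrix (query x class) and
#'   optionally `metrics`
#' @export
zeroShotClassify <- function(embeddings, reference, refLabels,
                             truth = NULL) {
    if (!nrow(reference)) stop("reference is empty")
    refLabels <- as.character(refLabels)
    classes <- sort(unique(refLabels))
    cent <- do.call(rbind, lapply(classes, function(cl) {
        rows <- refLabels == cl
        if (!any(rows)) stop("empty reference class: ", cl)
        colMeans(reference[rows, , drop = FALSE])
    }))
    nrm <- function(M) M / sqrt(rowSums(M * M))
    sim <- nrm(embeddings) %*% t(nrm(cent))
    colnames(sim) <- classes
    labels <- classes[max.col(sim, ties.method = "first")]
    out <- list(labels = labels, similarity = sim)
    if (!is.null(truth)) out$metrics <- evaluateClassifier(labels, truth)
    out
}
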