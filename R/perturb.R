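#' @include AllClasses.R AllGenerics.R model.R
NULL

#' In silico gene deletion
#'
#' Removes the gene's token from a cell sentence entirely (not a
#' zero-expression rewrite): every token ranked below it moves one
#' position forward and all other relative order is preserved. If the gene
#' is not in the sentence the sentence is returned unchanged with
#' `attr(, "perturbed") = FALSE`.
#'
#' @param sentence integer token vector (leading `[CLS]`)
#' @param gene gene identifier
#' @param vocab the [GeneVocabulary] of the sentence's corpus
#' @return the perturbed sentence; `attr(, "perturbed")` says whether the
#'   gene was present
#' @export
deleteGene <- function(sentence, gene, vocab) {
    tok <- tokenId(vocab, gene)
    if (is.na(tok)) stop("gene absent from vocabulary: ", gene)
    pos <- which(sentence == tok)
    out <- if (length(pos)) sentence[-pos] else sentence
    attr(out, "perturbed") <- length(pos) > 0L
    out
}

#' In silico gene activation
#'
#' Repositions the gene's token to rank 1 (immediately after `[CLS]`);
#' tokens formerly ranked above it each move one position back and all
#' other relative order is preserved. If the gene is absent from the
#' sentence its token is inserted at rank 1 and, if the sentence is at
#' `maxInput`, the last token is dropped; the insertion is flagged.
#'
#' @inheritParams deleteGene
#' @param maxInput sentence cap enforced on insertion
#' @return the perturbed sentence; `attr(, "perturbed")` is `TRUE`,
#'   `attr(, "inserted")` says whether the gene had to be inserted
#' @export
activateGene <- function(sentence, gene, vocab, maxInput = Inf) {
    tok <- tokenId(vocab, gene)
    if (is.na(tok)) stop("gene absent from vocabulary: ", gene)
    pos <- which(sentence == tok)
    inserted <- length(pos) == 0L
    body <- if (inserted) sentence[-1L] else sentence[-c(1L, pos)]
    out <- c(sentence[1L], tok, body)
    if (length(out) > maxInput) out <- out[seq_len(maxInput)]
    attr(out, "perturbed") <- TRUE
    attr(out, "inserted") <- inserted
    out
}

#' Cosine similarity of two embeddings
#'
#' @param u,v numeric vectors of equal dimension, both nonzero
#' @return cosine similarity in \[-1, 1\]
#' @export
cosineSimilarity <- function(u, v) {
    if (length(u) != length(v)) stop("dimension mismatch")
    nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
    if (nu == 0 || nv == 0) stop("cosine similarity of a zero vector")
    max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided test of location difference. For tie-free samples with
#' `length(a) + length(b) <= exactLimit` the p-value is computed by exact
#' enumeration of all assignments of ranks to the first sample; otherwise
#' the normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param a,b numeric samples (non-empty)
#' @param exactLimit largest combined size for exact enumeration
#' @return list with `U` (statistic of sample `a`), `p` (two-sided) and
#'   `method`
#' @export
wilcoxonRankSum <- function(a, b, exactLimit = 16L) {
    n <- length(a); m <- length(b)
    if (!n || !m) stop("both samples must be non-empty")
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    ties <- anyDuplicated(c(a, b)) > 0L
    if (!ties && n + m <= exactLimit) {
        # enumerate every choice of n ranks out of n+m and tabulate U
        combos <- utils::combn(n + m, n)
        Us <- colSums(combos) - n * (n + 1) / 2
        dev <- abs(Us - n * m / 2)
        p <- mean(dev >= abs(U - n * m / 2) - 1e-9)
        return(list(U = U, p = p, method = "exact"))
    }
    mu <- n * m / 2
    tieTab <- table(c(a, b))
    N <- n + m
    tieCorr <- sum(tieTab^3 - tieTab) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tieCorr)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
}

.meanEmbedding <- function(model, sents, layer, pooling) {
    colMeans(embedCells(model, sents, layer = layer, pooling = pooling))
}

.simToRef <- function(model, sents, ref, layer, pooling) {
    E <- embedCells(model, sents, layer = layer, pooling = pooling)
    apply(E, 1L, cosineSimilarity, v = ref)
}

#' Perturbation significance test for one gene
#'
#' Measures how far perturbing a gene moves start cells toward a goal cell
#' state: the reference is the mean embedding of the goal cells; the
#' specific distribution holds each start cell's cosine similarity to the
#' reference after perturbing `gene`; the control distribution perturbs,
#' in each start cell, one uniformly drawn gene from that cell's own
#' expressed genes (excluding `gene`), repeated `nRandom` times and pooled.
#' The two distributions are compared with the two-sided Wilcoxon rank-sum
#' test; significance is declared at p < 0.05.
#'
#' @param model a trained [ModelState]
#' @param gene gene identifier to perturb
#' @param op `"delete"` or `"activate"`
#' @param startCells,goalCells lists of cell sentences
#' @param vocab the [GeneVocabulary]
#' @param nRandom number of random-control repetitions (>= 1)
#' @param seed seed for the control draws
#' @param layer,pooling embedding extraction settings (see [embedCells()])
#' @return one-row [S4Vectors::DataFrame]: gene, op, mean similarity under
#'   specific perturbation / random control / no perturbation, the shift
#'   (specific - unperturbed), U, p and the significance flag
#' @export
perturbationTest <- function(model, gene, op = c("delete", "activate"),
                             startCells, goalCells, vocab, nRandom = 10L,
                             seed = 1L, layer = model@config@nBlocks,
                             pooling = "mean") {
    op <- match.arg(op)
    if (!length(startCells) || !length(goalCells))
        stop("start and goal cell sets must be non-empty")
    if (nRandom < 1L) stop("nRandom must be >= 1")
    set.seed(seed)
    tok <- tokenId(vocab, gene)
    if (is.na(tok)) stop("gene absent from vocabulary: ", gene)
    maxInput <- model@config@maxInput
    perturb <- function(s, g) {
        if (op == "delete") deleteGene(s, g, vocab)
        else activateGene(s, g, vocab, maxInput)
    }
    present <- vapply(startCells, function(s) tok %in% s, logical(1))
    if (op == "delete" && !any(present))
        stop("nothing to perturb: ", gene, " absent from every start cell")

    ref <- .meanEmbedding(model, goalCells, layer, pooling)
    unpert <- .simToRef(model, startCells, ref, layer, pooling)
    spec <- .simToRef(model, lapply(startCells, perturb, g = gene),
                      ref, layer, pooling)
    ctrl <- numeric()
    geneNames <- vocabGenes(vocab)
    for (r in seq_len(nRandom)) {
        ctrlSents <- lapply(startCells, function(s) {
            pool <- setdiff(s[s >= .N_SPECIAL], tok)
            if (!length(pool)) return(s)
            rg <- geneNames[pool[sample.int(length(pool), 1L)] -
                            .N_SPECIAL + 1L]
            perturb(s, rg)
        })
        ctrl <- c(ctrl, .simToRef(model, ctrlSents, ref, layer, pooling))
    }
    w <- wilcoxonRankSum(spec, ctrl)
    S4Vectors::DataFrame(
        gene = gene, op = op,
        mean_specific = mean(spec), mean_random = mean(ctrl),
        mean_unperturbed = mean(unpert),
        shift = mean(spec) - mean(unpert),
        U = w$U, p_value = w$p, significant = w$p < 0.05)
}

#' Screen candidate genes by perturbation effect
#'
#' Runs [perturbationTest()] for every candidate gene and returns the
#' reports sorted by shift (descending), ties broken by p-value
#' (ascending) then gene id. Benjamini-Hochberg q-values are appended.
#' A fine-tuned classifier accuracy below `accuracyGate` aborts unless
#' `overrideGate` is set — perturbation readouts from a model that cannot
#' separate the states being compared are not interpretable.
#'
#' @inheritParams perturbationTest
#' @param candidates character vector of candidate genes (non-empty)
#' @param accuracy held-out accuracy of the fine-tuned model feeding the
#'   screen (from `finetuneModel()$metrics$accuracy`), checked against the
#'   gate; `NULL` skips the check
#' @param accuracyGate minimum required accuracy (published gate: 0.90)
#' @param overrideGate proceed despite a failing gate
#' @return [S4Vectors::DataFrame] with one row per candidate; genes whose
#'   individual test errored get `NA` statistics and the message in
#'   `error`
#' @export
screenGenes <- function(model, startCells, goalCells, candidates,
                        op = c("delete", "activate"), vocab, nRandom = 10L,
                        seed = 1L, layer = model@config@nBlocks,
                        pooling = "mean", accuracy = NULL,
                        accuracyGate = 0.90, overrideGate = FALSE) {
    op <- match.arg(op)
    if (!length(candidates)) stop("candidate set is empty")
    if (!length(goalCells)) stop("goal cell set is empty")
    if (!is.null(accuracy) && accuracy < accuracyGate && !overrideGate)
        stop(sprintf(
            "fine-tuned accuracy %.3f is below the %.2f gate; pass ",
            accuracy, accuracyGate), "overrideGate = TRUE to proceed anyway")
    candidates <- as.character(candidates)
    # per-gene seeds keyed to the sorted candidate order, so permuting the
    # candidate list cannot change any gene's report
    seeds <- seed + match(candidates, sort(unique(candidates))) - 1L
    rows <- vector("list", length(candidates))
    for (i in order(candidates)) {
        rows[[i]] <- tryCatch({
            r <- perturbationTest(model, candidates[i], op, startCells,
                                  goalCells, vocab, nRandom,
                                  seed = seeds[i], layer = layer,
                                  pooling = pooling)
            r$error <- NA_character_
            r
        }, error = function(e) S4Vectors::DataFrame(
            gene = candidates[i], op = op, mean_specific = NA_real_,
            mean_random = NA_real_, mean_unperturbed = NA_real_,
            shift = NA_real_, U = NA_real_, p_value = NA_real_,
            significant = NA, error = conditionMessage(e)))
    }
    tab <- do.call(rbind, rows)
    tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
    ord <- order(-tab$shift, tab$p_value, tab$gene, na.last = TRUE)
    tab[ord, ]
}
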