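#' @include AllClasses.R
NULL

# token ids reserved for the three specials
.SPECIALS <- c("[PAD]" = 0L, "[MASK]" = 1L, "[CLS]" = 2L)
.PAD <- 0L
.MASK <- 1L
.CLS <- 2L
.N_SPECIAL <- 3L

#' Accessors for scRankformer classes
#'
#' `sentences()` returns the list of token sequences of a corpus;
#' `cellData()` its per-cell metadata; `vocabGenes()` the gene identifiers
#' of a vocabulary in token order; `vocabSize()` the total token count
#' (specials included); `tokenId()`/`geneOf()` translate between gene
#' identifiers and token ids; `specialTokens()` the reserved special-token
#' map; `encoderConfigOf()` the architecture of a model;
#' `forwardMap()`/`reverseMap()` the two directed views of an ortholog
#' table.
#'
#' @param x the object
#' @param genes,tokens identifiers / token ids to translate
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sentences", function(x) standardGeneric("sentences"))
#' @rdname accessors
#' @export
setMethod("sentences", "TokenizedCorpus", function(x) x@sentences)

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setMethod("cellData", "TokenizedCorpus", function(x) x@cellData)

#' @rdname accessors
#' @export
setGeneric("vocabGenes", function(x) standardGeneric("vocabGenes"))
#' @rdname accessors
#' @export
setMethod("vocabGenes", "GeneVocabulary", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))
#' @rdname accessors
#' @export
setMethod("vocabSize", "GeneVocabulary",
          function(x) length(x@genes) + .N_SPECIAL)
#' @rdname accessors
#' @export
setMethod("vocabSize", "EncoderConfig", function(x) x@vocabSize)

#' @rdname accessors
#' @export
specialTokens <- function() .SPECIALS

#' @rdname accessors
#' @export
setGeneric("tokenId", function(x, genes) standardGeneric("tokenId"))
#' @rdname accessors
#' @export
setMethod("tokenId", "GeneVocabulary", function(x, genes) {
    i <- match(genes, x@genes)
    out <- i + .N_SPECIAL - 1L
    names(out) <- genes
    out
})

#' @rdname accessors
#' @export
setGeneric("geneOf", function(x, tokens) standardGeneric("geneOf"))
#' @rdname accessors
#' @export
setMethod("geneOf", "GeneVocabulary", function(x, tokens) {
    out <- rep(NA_character_, length(tokens))
    sp <- match(tokens, .SPECIALS)
    out[!is.na(sp)] <- names(.SPECIALS)[sp[!is.na(sp)]]
    g <- tokens >= .N_SPECIAL
    out[g] <- x@genes[tokens[g] - .N_SPECIAL + 1L]
    out
})

#' @rdname accessors
#' @export
setGeneric("encoderConfigOf", function(x) standardGeneric("encoderConfigOf"))
#' @rdname accessors
#' @export
setMethod("encoderConfigOf", "ModelState", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("forwardMap", function(x) standardGeneric("forwardMap"))
#' @rdname accessors
#' @export
setMethod("forwardMap", "OrthologTable", function(x) x@forward)

#' @rdname accessors
#' @export
setGeneric("reverseMap", function(x) standardGeneric("reverseMap"))
#' @rdname accessors
#' @export
setMethod("reverseMap", "OrthologTable", function(x) {
    stats::setNames(names(x@forward), unname(x@forward))
})

setMethod("show", "GeneVocabulary", function(object) {
    cat("GeneVocabulary:", length(object@genes), "genes +",
        .N_SPECIAL, "specials ([PAD]=0, [MASK]=1, [CLS]=2)\n")
})

setMethod("show", "TokenizedCorpus", function(object) {
    n <- length(object@sentences)
    len <- if (n) lengths(object@sentences) else 0L
    cat("TokenizedCorpus:", n, "cell sentences",
        sprintf("(length %d-%d, median %.0f)\n",
                min(len), max(len), stats::median(len)))
    cat("  vocabulary hash:", object@vocabHash, "\n")
    if (ncol(object@cellData))
        cat("  cell metadata:", paste(colnames(object@cellData), collapse = ", "), "\n")
})

setMethod("show", "EncoderConfig", function(object) {
    cat(sprintf(
        "EncoderConfig: %d blocks, %d heads, dim %d (ff x%d), %s, dropout %.3g\n",
        object@nBlocks, object@nHeads, object@embedDim, object@ffMult,
        object@activation, object@dropout))
    cat(sprintf("  max input %d tokens, vocab %d, classes %d\n",
                object@maxInput, object@vocabSize, object@nClasses))
})

setMethod("show", "ModelState", function(object) {
    show(object@config)
    np <- sum(vapply(rapply(object@params, identity, how = "unlist"),
                     length, 1L))
    cat(sprintf("ModelState: %s parameters; trained stages: %s\n",
                format(np, big.mark = ","),
                paste(names(object@provenance$stages %||% list("none")),
                      collapse = ", ")))
})

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport:", length(object@keptIndex), "cells kept,",
        nrow(object@removed), "removed\n")
    if (length(object@countsPerFilter)) {
        tallies <- paste(names(object@countsPerFilter),
                         object@countsPerFilter, sep = "=", collapse = ", ")
        cat("  filters fired:", tallies, "\n")
    }
})

setMethod("show", "OrthologTable", function(object) {
    cat("OrthologTable:", length(object@forward), "one-to-one pairs;",
        length(object@unmappedHuman), "human /",
        length(object@unmappedMouse), "mouse ids unmapped;",
        sum(object@provenance$tie_break), "tie-breaks applied\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
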