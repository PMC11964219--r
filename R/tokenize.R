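#' @include AllClasses.R AllGenerics.R
NULL

# FNV-1a hash over a character vector, hex string; used to fingerprint
# vocabularies so corpora and checkpoints can be compatibility-checked
.fnv1a <- function(strings) {
    bytes <- as.integer(charToRaw(paste(strings, collapse = "\x1f")))
    h <- 2166136261
    prime <- 16777619
    for (b in bytes) {
        hx <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
        # multiply by the FNV prime modulo 2^32 in exact double arithmetic
        lo <- (hx %% 2^16) * prime
        hi <- ((hx %/% 2^16) * prime) %% 2^16
        h <- (lo + hi * 2^16) %% 2^32
    }
    paste0(sprintf("%04x", as.integer(h %/% 2^16)),
           sprintf("%04x", as.integer(h %% 2^16)))
}

#' Hash of a vocabulary's gene list
#' @param vocab a [GeneVocabulary]
#' @export
vocabHash <- function(vocab) .fnv1a(vocabGenes(vocab))

#' Build the gene-token vocabulary
#'
#' The vocabulary covers exactly the genes present in the median table
#' (genes never expressed in the corpus have no median and receive no
#' token). Special tokens occupy the reserved ids `[PAD]=0`, `[MASK]=1`,
#' `[CLS]=2`; gene tokens follow in lexicographic order of identifier, so
#' the mapping is deterministic for a given gene set.
#'
#' @param geneIds candidate gene identifiers (must be unique)
#' @param medians named nonzero-median table from [computeGeneMedians()];
#'   if supplied, the vocabulary is restricted to its genes
#' @return a [GeneVocabulary]
#' @export
buildVocabulary <- function(geneIds, medians = NULL) {
    if (anyDuplicated(geneIds))
        stop("duplicate gene identifiers: ",
             paste(utils::head(unique(geneIds[duplicated(geneIds)]), 5),
                   collapse = ", "))
    if (!is.null(medians)) geneIds <- intersect(geneIds, names(medians))
    methods::new("GeneVocabulary",
                 genes = sort(as.character(geneIds), method = "radix"))
}

#' @rdname buildVocabulary
#' @param path JSON file path
#' @export
saveVocabulary <- function(vocab, path) {
    jsonlite::write_json(list(specials = as.list(specialTokens()),
                              genes = vocabGenes(vocab)),
                         path, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname buildVocabulary
#' @param vocab a [GeneVocabulary]
#' @export
loadVocabulary <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("GeneVocabulary", genes = as.character(obj$genes))
}

#' Rank value encoding of one cell
#'
#' Genes with zero count are excluded; each remaining gene is scored
#' `count / median` against its corpus-wide nonzero median; genes are
#' sorted by descending score (ties broken by ascending token id, so the
#' encoding is deterministic); `[CLS]` is prepended and the sentence is
#' truncated to `maxInput` tokens in total (`[CLS]` included, so at most
#' `maxInput - 1` gene tokens).
#'
#' @param expression named non-negative count vector for one cell
#' @param medians nonzero-median table ([computeGeneMedians()])
#' @param vocab a [GeneVocabulary]
#' @param maxInput sentence cap, `[CLS]` included (>= 2); the published
#'   positional capacity is 2048
#' @param normalize `TRUE` (default) scores `count / median`; `FALSE` gives
#'   raw-rank mode (scores are the raw counts), provided for ablation
#' @param onMissing genes absent from the vocabulary/medians: `"skip"`
#'   drops them with a warning, `"error"` aborts
#' @return integer token vector, `[CLS]` first
#' @export
encodeCell <- function(expression, medians, vocab, maxInput = 2048L,
                       normalize = TRUE, onMissing = c("skip", "error")) {
    onMissing <- match.arg(onMissing)
    if (maxInput < 2L) stop("maxInput must be >= 2")
    if (any(expression < 0)) stop("expression must be non-negative")
    nz <- expression[expression > 0]
    tok <- tokenId(vocab, names(nz))
    missing <- is.na(tok)
    if (any(missing)) {
        if (onMissing == "error")
            stop("genes absent from vocabulary: ",
                 paste(utils::head(names(nz)[missing], 5), collapse = ", "))
        warning(sum(missing), " expressed gene(s) absent from vocabulary; skipped")
        nz <- nz[!missing]; tok <- tok[!missing]
    }
    if (normalize) {
        med <- medians[names(nz)]
        bad <- is.na(med)
        if (any(bad)) {
            if (onMissing == "error")
                stop("genes absent from median table: ",
                     paste(utils::head(names(nz)[bad], 5), collapse = ", "))
            warning(sum(bad), " expressed gene(s) absent from medians; skipped")
            nz <- nz[!bad]; tok <- tok[!bad]; med <- med[!bad]
        }
        score <- as.numeric(nz) / as.numeric(med)
    } else score <- as.numeric(nz)
    ord <- order(-score, tok, method = "radix")
    unname(c(.CLS, tok[ord])[seq_len(min(1L + length(ord), maxInput))])
}

#' Rank value encoding of a whole dataset
#'
#' Applies [encodeCell()] to every cell and assembles a [TokenizedCorpus]
#' carrying the per-cell metadata, the vocabulary hash and the tokenizer
#' settings.
#'
#' @inheritParams encodeCell
#' @param dataset a (post-QC) [RankCellDataset]
#' @return a [TokenizedCorpus]
#' @export
encodeDataset <- function(dataset, medians, vocab, maxInput = 2048L,
                          normalize = TRUE, onMissing = c("skip", "error")) {
    onMissing <- match.arg(onMissing)
    counts <- methods::as(SummarizedExperiment::assay(dataset, "counts"),
                          "CsparseMatrix")
    genes <- rownames(counts)
    tokAll <- tokenId(vocab, genes)
    medAll <- medians[genes]
    n <- ncol(counts)
    sents <- vector("list", n)
    p <- counts@p
    reported <- FALSE
    for (j in seq_len(n)) {
        idx <- if (p[j + 1L] > p[j]) (p[j] + 1L):p[j + 1L] else integer()
        ri <- counts@i[idx] + 1L
        x <- counts@x[idx]
        keep <- x > 0
        ri <- ri[keep]; x <- x[keep]
        tok <- tokAll[ri]
        score <- if (normalize) x / medAll[ri] else x
        bad <- is.na(tok) | is.na(score)
        if (any(bad)) {
            if (onMissing == "error")
                stop("genes absent from vocabulary/medians: ",
                     paste(utils::head(genes[ri[bad]], 5), collapse = ", "))
            if (!reported) {
                warning("expressed genes absent from vocabulary/medians ",
                        "were skipped")
                reported <- TRUE
            }
            tok <- tok[!bad]; score <- score[!bad]
        }
        ord <- order(-score, tok, method = "radix")
        sents[[j]] <- unname(c(.CLS, tok[ord])[
            seq_len(min(1L + length(ord), maxInput))])
    }
    names(sents) <- colnames(counts)
    methods::new("TokenizedCorpus", sentences = sents,
        cellData = SummarizedExperiment::colData(dataset),
        vocabHash = vocabHash(vocab),
        tokenizer = list(maxInput = as.integer(maxInput),
                         normalize = normalize))
}
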