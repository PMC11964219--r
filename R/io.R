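#' @include AllClasses.R AllGenerics.R tokenize.R
NULL

#' Read a raw count dataset
#'
#' Supported on-disk forms are a MatrixMarket triple (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv` in one directory, genes x cells) and a
#' dense CSV (genes in rows). HDF5-backed forms (`h5ad`, `loom`) are not
#' readable in this installation and raise an informative error. On load,
#' Ensembl version suffixes are stripped and, when `genes.tsv` carries no
#' explicit `mito` column, mitochondrial genes are flagged by a
#' case-insensitive `mt-` name prefix. Side tables may carry a header row
#' (`gene_id`/`cell_id` first) or be headerless id lists. If the matrix
#' dimensions match the gene and cell lists only after transposition the
#' matrix is transposed; if both interpretations fit, an error demands an
#' explicit orientation.
#'
#' @param path directory (mtx) or file (csv)
#' @param format `"mtx"` or `"csv"` (`"h5ad"`/`"loom"` error)
#' @param orientation `"genes_x_cells"` (default), `"cells_x_genes"`, or
#'   `"auto"`
#' @return a [RankCellDataset]
#' @export
readDataset <- function(path, format = c("mtx", "csv", "h5ad", "loom"),
                        orientation = c("auto", "genes_x_cells",
                                        "cells_x_genes")) {
    format <- match.arg(format)
    orientation <- match.arg(orientation)
    if (format %in% c("h5ad", "loom"))
        stop("'", format, "' input requires HDF5 bindings that are not ",
             "installed; convert to a MatrixMarket triple (e.g. with ",
             "scanpy/anndata) and use format = 'mtx'")
    if (!file.exists(path)) stop("no such path: ", path)
    if (format == "mtx") {
        mtx <- file.path(path, "matrix.mtx")
        mat <- tryCatch(methods::as(Matrix::readMM(mtx), "CsparseMatrix"),
                        error = function(e)
                            stop("failed to parse ", mtx, ": ",
                                 conditionMessage(e)))
        genesTab <- .readSideTable(file.path(path, "genes.tsv"), "gene_id")
        cellsTab <- .readSideTable(file.path(path, "barcodes.tsv"),
                                   "cell_id")
        geneIds <- stripEnsemblVersion(genesTab$gene_id)
        cellIds <- cellsTab$cell_id
        fits <- nrow(mat) == length(geneIds) && ncol(mat) == length(cellIds)
        fitsT <- ncol(mat) == length(geneIds) && nrow(mat) == length(cellIds)
        if (orientation == "cells_x_genes") mat <- Matrix::t(mat)
        else if (orientation == "auto") {
            if (fits && fitsT && length(geneIds) != length(cellIds))
                stop("orientation inconsistent with gene/cell lists")
            if (fits && fitsT)
                stop("matrix is square: orientation is ambiguous, pass ",
                     "orientation = 'genes_x_cells' or 'cells_x_genes'")
            if (fitsT && !fits) mat <- Matrix::t(mat)
            else if (!fits)
                stop("matrix dimensions match neither genes x cells nor ",
                     "cells x genes")
        }
        dimnames(mat) <- list(geneIds, cellIds)
        mito <- if ("mito" %in% colnames(genesTab))
            as.logical(genesTab$mito) else grepl("^mt-", geneIds,
                                                 ignore.case = TRUE)
        meta <- cellsTab[setdiff(colnames(cellsTab), "cell_id")]
        cd <- S4Vectors::DataFrame(meta, row.names = cellIds)
    } else {
        df <- tryCatch(utils::read.csv(path, row.names = 1,
                                       check.names = FALSE),
                       error = function(e)
                           stop("failed to parse ", path, ": ",
                                conditionMessage(e)))
        mat <- methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE),
                           "CsparseMatrix")
        rownames(mat) <- stripEnsemblVersion(rownames(mat))
        mito <- grepl("^mt-", rownames(mat), ignore.case = TRUE)
        cd <- S4Vectors::DataFrame(row.names = colnames(mat))
    }
    .buildDataset(mat, rownames(mat), mito, cd)
}

.readSideTable <- function(path, idName) {
    if (!file.exists(path)) stop("missing side table: ", path)
    first <- readLines(path, n = 1L)
    hasHeader <- startsWith(first, idName)
    df <- utils::read.delim(path, header = hasHeader,
                            stringsAsFactors = FALSE)
    if (!hasHeader) colnames(df)[1] <- idName
    df
}

#' Write a dataset as a MatrixMarket triple
#'
#' @param dataset a [RankCellDataset]
#' @param dir output directory (created if needed)
#' @export
writeDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- SummarizedExperiment::assay(dataset, "counts")
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(
        data.frame(gene_id = rownames(dataset),
                   mito = SummarizedExperiment::rowData(dataset)$mito),
        file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(dataset))
    utils::write.table(
        cbind(cell_id = colnames(dataset), cd),
        file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}

#' Arrow serialization of a tokenized corpus
#'
#' `writeCorpusArrow()` writes a columnar dataset (`corpus.feather` with
#' token ids, sentence length, cell id and metadata columns) plus a
#' `manifest.json` recording the vocabulary hash and tokenizer settings.
#' `readCorpusArrow()` refuses to load a corpus whose vocabulary hash does
#' not match the supplied vocabulary — silently remapping token ids across
#' vocabularies would corrupt every downstream result.
#'
#' @param corpus a [TokenizedCorpus]
#' @param path output directory
#' @return the manifest (invisibly for the writer)
#' @export
writeCorpusArrow <- function(corpus, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sents <- sentences(corpus)
    tab <- data.frame(cell_id = names(sents) %||%
                          sprintf("cell%05d", seq_along(sents)),
                      length = lengths(sents))
    tab$tokens <- unname(sents)
    meta <- as.data.frame(cellData(corpus))
    for (cl in colnames(meta)) tab[[cl]] <- meta[[cl]]
    arrow::write_feather(arrow::arrow_table(tab),
                         file.path(path, "corpus.feather"))
    manifest <- list(vocab_hash = corpus@vocabHash,
                     tokenizer = corpus@tokenizer,
                     n_cells = length(sents))
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' @rdname writeCorpusArrow
#' @param vocab the [GeneVocabulary] the reader intends to use; its hash
#'   must match the manifest
#' @export
readCorpusArrow <- function(path, vocab = NULL) {
    manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                    simplifyVector = TRUE)
    if (!is.null(vocab) && !identical(vocabHash(vocab),
                                      manifest$vocab_hash))
        stop("vocabulary hash mismatch: corpus was tokenized with ",
             manifest$vocab_hash, ", supplied vocabulary is ",
             vocabHash(vocab))
    tab <- as.data.frame(arrow::read_feather(file.path(path,
                                                       "corpus.feather")))
    sents <- lapply(tab$tokens, as.integer)
    names(sents) <- tab$cell_id
    metaCols <- setdiff(colnames(tab), c("cell_id", "length", "tokens"))
    methods::new("TokenizedCorpus", sentences = sents,
        cellData = S4Vectors::DataFrame(tab[metaCols],
                                        row.names = tab$cell_id),
        vocabHash = manifest$vocab_hash,
        tokenizer = lapply(as.list(manifest$tokenizer), function(x)
            if (is.numeric(x)) as.integer(x) else x))
}

#' Write a filter report as JSON
#' @param report a [FilterReport]
#' @param path output file
#' @export
writeFilterReport <- function(report, path) {
    jsonlite::write_json(list(
        kept = report@keptIndex,
        removed = as.data.frame(report@removed),
        counts_per_filter = as.list(report@countsPerFilter)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

# ---- pipeline configuration -------------------------------------------

.configSchema <- list(
    seed = NULL,
    qc = c("sd_multiplier", "min_genes_per_cell", "max_total_counts",
           "two_sided", "mito_mode"),
    tokenizer = c("max_input", "normalize"),
    encoder = c("max_input", "n_blocks", "n_heads", "embed_dim", "ff_mult",
                "dropout", "n_classes", "tie_mlm"),
    pretrain = c("epochs", "max_lr", "warmup_steps", "scheduler",
                 "batch_size", "weight_decay", "mask_rate", "mask_mode",
                 "freeze_blocks", "seed"),
    finetune = c("epochs", "max_lr", "warmup_steps", "scheduler",
                 "batch_size", "weight_decay", "mask_rate", "mask_mode",
                 "freeze_blocks", "seed", "split_fraction", "label_column"),
    perturbation = c("op", "n_random", "layer", "pooling", "accuracy_gate"),
    paths = c("corpus", "medians", "vocabulary", "checkpoint", "out"))

#' Read / write the pipeline configuration
#'
#' A nested YAML file with sections `seed`, `qc`, `tokenizer`, `encoder`,
#' `pretrain`, `finetune`, `perturbation` and `paths`. Unknown keys are
#' rejected with their location, and the representation round-trips
#' losslessly.
#'
#' @param path YAML file
#' @return named list of sections
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    bad <- setdiff(names(cfg), names(.configSchema))
    if (length(bad))
        stop("unknown configuration key(s) at top level: ",
             paste(bad, collapse = ", "))
    for (sec in names(cfg)) {
        allowed <- .configSchema[[sec]]
        if (is.null(allowed)) next
        extra <- setdiff(names(cfg[[sec]]), allowed)
        if (length(extra))
            stop("unknown configuration key(s) in section '", sec, "': ",
                 paste(extra, collapse = ", "))
    }
    cfg
}

#' @rdname readPipelineConfig
#' @param config named list of sections
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
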