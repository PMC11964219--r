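#' @include AllClasses.R AllGenerics.R
NULL

#' Quality-control thresholds
#'
#' Constructor for [QCThresholds]; defaults follow the published filter
#' list: 3-SD bands on total and mitochondrial counts, a minimum of 7
#' detected genes per cell, and an absolute cap of 20,000 total counts
#' (read as a strict inequality).
#'
#' @param sdMultiplier width of the standard-deviation bands
#' @param minGenesPerCell minimum detected genes; cells with fewer are removed
#' @param maxTotalCounts absolute cap on per-cell total counts (strict `>`)
#' @param twoSided if `TRUE` (default) the SD bands are |x - mean| > k sd;
#'   if `FALSE`, upper tail only
#' @param mitoMode `"sum"` (summed mitochondrial counts, default) or
#'   `"fraction"` (mitochondrial share of the cell total)
#' @export
qcThresholds <- function(sdMultiplier = 3, minGenesPerCell = 7L,
                         maxTotalCounts = 20000, twoSided = TRUE,
                         mitoMode = c("sum", "fraction")) {
    methods::new("QCThresholds", sdMultiplier = as.numeric(sdMultiplier),
                 minGenesPerCell = as.integer(minGenesPerCell),
                 maxTotalCounts = as.numeric(maxTotalCounts),
                 twoSided = isTRUE(twoSided),
                 mitoMode = match.arg(mitoMode))
}

.cellTotals <- function(dataset, mitoMode = "sum") {
    counts <- SummarizedExperiment::assay(dataset, "counts")
    mito <- SummarizedExperiment::rowData(dataset)$mito
    total <- Matrix::colSums(counts)
    mitoSum <- Matrix::colSums(counts[mito, , drop = FALSE])
    mitoVal <- if (mitoMode == "fraction")
        ifelse(total > 0, mitoSum / total, 0) else mitoSum
    list(total = total, mito = mitoVal,
         detected = Matrix::colSums(counts > 0))
}

#' Pre-filter statistics of one dataset
#'
#' Computes the mean and population standard deviation (divide by n, not
#' n - 1) of per-cell total counts and per-cell mitochondrial expression
#' over every cell of the dataset, before any removal. These statistics
#' anchor the SD-band filters of [applyQCFilters()].
#'
#' @param dataset a non-empty [RankCellDataset]
#' @param mitoMode `"sum"` or `"fraction"`, see [qcThresholds()]
#' @return a [QCStats]
#' @export
datasetStats <- function(dataset, mitoMode = "sum") {
    if (ncol(dataset) == 0L) stop("dataset has no cells")
    t <- .cellTotals(dataset, mitoMode)
    popSD <- function(x) sqrt(mean((x - mean(x))^2))
    methods::new("QCStats",
        meanTotal = mean(t$total), sdTotal = popSD(t$total),
        meanMito = mean(t$mito), sdMito = popSD(t$mito),
        nCells = ncol(dataset))
}

#' Apply the four per-dataset cell filters
#'
#' A cell is removed iff any of the four predicates fires, all evaluated
#' against the supplied pre-filter statistics in a single conjunctive pass
#' (no sequential re-estimation): total counts outside the k-SD band;
#' mitochondrial expression outside its k-SD band; detected genes below the
#' minimum; total counts strictly above the absolute cap. The report
#' records every predicate that fired for each removed cell.
#'
#' @param dataset a [RankCellDataset]
#' @param stats the [QCStats] of this dataset (defaults to computing them
#'   here); must match the dataset's cell count
#' @param thresholds a [QCThresholds]
#' @return list with `dataset` (retained cells) and `report`
#'   (a [FilterReport])
#' @export
applyQCFilters <- function(dataset, stats = datasetStats(dataset,
                                                         thresholds@mitoMode),
                           thresholds = qcThresholds()) {
    if (stats@nCells != ncol(dataset))
        stop("stats were computed on ", stats@nCells,
             " cells but the dataset has ", ncol(dataset))
    t <- .cellTotals(dataset, thresholds@mitoMode)
    k <- thresholds@sdMultiplier
    dev <- function(x, m, s) if (thresholds@twoSided) abs(x - m) > k * s
                             else x - m > k * s
    fired <- cbind(
        sd_total = dev(t$total, stats@meanTotal, stats@sdTotal),
        sd_mito = dev(t$mito, stats@meanMito, stats@sdMito),
        min_genes = t$detected < thresholds@minGenesPerCell,
        max_total = t$total > thresholds@maxTotalCounts)
    drop <- rowSums(fired) > 0
    ids <- colnames(dataset)
    removed <- S4Vectors::DataFrame(
        cell = ids[drop],
        filters = vapply(which(drop), function(i)
            paste(colnames(fired)[fired[i, ]], collapse = ","), character(1)))
    report <- methods::new("FilterReport",
        keptIndex = ids[!drop], removed = removed,
        countsPerFilter = stats::setNames(as.integer(colSums(fired)),
                                          colnames(fired)))
    list(dataset = dataset[, !drop], report = report)
}

#' Corpus-wide nonzero gene medians
#'
#' For every gene, the median of its strictly positive counts pooled over
#' all cells of all supplied datasets. Genes never expressed anywhere are
#' absent from the table. These medians normalize expression during rank
#' value encoding so that ubiquitously high housekeeping genes do not
#' dominate every cell sentence.
#'
#' @param corpus a [RankCellDataset] or a list of them (post-QC); all
#'   datasets must share one gene universe
#' @return named numeric vector, gene id -> nonzero median
#' @export
computeGeneMedians <- function(corpus) {
    if (methods::is(corpus, "RankCellDataset")) corpus <- list(corpus)
    genes <- rownames(corpus[[1]])
    vals <- vector("list", length(corpus))
    for (i in seq_along(corpus)) {
        if (!identical(rownames(corpus[[i]]), genes)) {
            off <- union(setdiff(rownames(corpus[[i]]), genes),
                         setdiff(genes, rownames(corpus[[i]])))
            stop("gene universe mismatch across datasets; offending ids: ",
                 paste(utils::head(off, 5), collapse = ", "),
                 if (length(off) > 5) ", ...")
        }
        m <- methods::as(SummarizedExperiment::assay(corpus[[i]], "counts"),
                         "CsparseMatrix")
        vals[[i]] <- data.frame(gene = m@i + 1L, x = m@x)[m@x > 0, ]
    }
    pooled <- do.call(rbind, vals)
    if (!nrow(pooled)) return(stats::setNames(numeric(), character()))
    med <- vapply(split(pooled$x, pooled$gene), stats::median, numeric(1))
    stats::setNames(as.numeric(med), genes[as.integer(names(med))])
}
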