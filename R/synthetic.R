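#' @include AllClasses.R AllGenerics.R
NULL

#' Configure the synthetic single-cell corpus generator
#'
#' Builds a [SyntheticConfig] describing a negative-binomial count matrix
#' with planted structure. Genes are laid out as `nCellTypes` disjoint
#' cell-type programs of `programSize` genes each (occupying the first gene
#' indices), followed by background genes; the trailing
#' `ceiling(mitoFraction * nGenes)` genes are flagged mitochondrial and are
#' kept outside every program. A cell of type *t* draws its program-*t*
#' genes with mean `baselineMean * programFold` and everything else at
#' `baselineMean`, all with NB dispersion `dispersion`
#' (`variance = mu + dispersion * mu^2`). In two-condition designs,
#' condition-B cells additionally draw `causalGenes` at
#' `baselineMean * causalFold`.
#'
#' @param nCells,nGenes matrix size (default 1000 x 500)
#' @param nCellTypes,programSize,programFold cell-type program layout and
#'   multiplicative expression boost
#' @param baselineMean mean count per gene outside any program
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion)
#' @param mitoFraction fraction of genes flagged mitochondrial
#' @param nConditions 1 or 2
#' @param causalGenes gene identifiers separating the two conditions
#' @param causalFold fold change applied to causal genes in condition B
#' @param seed integer random seed; identical config + seed gives
#'   bit-identical output
#' @return a validated [SyntheticConfig]
#' @export
syntheticConfig <- function(nCells = 1000L, nGenes = 500L, nCellTypes = 4L,
                            programSize = 25L, programFold = 8,
                            baselineMean = 0.5, dispersion = 0.1,
                            mitoFraction = 0.05, nConditions = 1L,
                            causalGenes = character(), causalFold = 1,
                            seed = 1L) {
    cfg <- methods::new("SyntheticConfig",
        nCells = as.integer(nCells), nGenes = as.integer(nGenes),
        nCellTypes = as.integer(nCellTypes),
        programSize = as.integer(programSize),
        programFold = as.numeric(programFold),
        baselineMean = as.numeric(baselineMean),
        dispersion = as.numeric(dispersion),
        mitoFraction = as.numeric(mitoFraction),
        nConditions = as.integer(nConditions),
        causalGenes = as.character(causalGenes),
        causalFold = as.numeric(causalFold), seed = as.integer(seed))
    nMito <- ceiling(cfg@mitoFraction * cfg@nGenes)
    if (cfg@programSize * cfg@nCellTypes + nMito > cfg@nGenes)
        stop("programs and mitochondrial genes overlap: reduce programSize, ",
             "nCellTypes or mitoFraction")
    cfg
}

#' Ensembl-style synthetic gene identifiers
#' @param n number of identifiers
#' @keywords internal
.syntheticGeneIds <- function(n) {
    if (n == 0L) return(character())
    sprintf("ENSMUSG%011d", seq_len(n))
}

# program membership: gene indices of each cell-type program
.programIndex <- function(cfg) {
    if (cfg@nCellTypes == 0L || cfg@programSize == 0L) return(list())
    lapply(seq_len(cfg@nCellTypes), function(t)
        ((t - 1L) * cfg@programSize + 1L):(t * cfg@programSize))
}

.buildDataset <- function(counts, geneIds, mito, cellMeta) {
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(mito = mito, row.names = geneIds),
        colData = cellMeta)
    methods::as(sce, "RankCellDataset")
}

# shared NB sampler: mean matrix -> sparse integer counts
.sampleCounts <- function(mu, dispersion) {
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / dispersion),
                     nrow = nrow(mu))
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

.simulate <- function(cfg, conditionDesign = FALSE) {
    set.seed(cfg@seed)
    geneIds <- .syntheticGeneIds(cfg@nGenes)
    nMito <- ceiling(cfg@mitoFraction * cfg@nGenes)
    mito <- rep(FALSE, cfg@nGenes)
    if (nMito > 0L) mito[(cfg@nGenes - nMito + 1L):cfg@nGenes] <- TRUE

    n <- cfg@nCells
    cellIds <- if (n) sprintf("cell%05d", seq_len(n)) else character()
    type <- if (cfg@nCellTypes > 0L && n > 0L)
        paste0("type", rep_len(seq_len(cfg@nCellTypes), n)) else
        rep("type1", n)
    condition <- rep("A", n)
    # block assignment, deliberately decoupled from the cell-type cycle so
    # condition is not confounded with type programs
    if (conditionDesign && n > 0L)
        condition[seq_len(n) > n / 2] <- "B"

    mu <- matrix(cfg@baselineMean, nrow = cfg@nGenes, ncol = n)
    progs <- .programIndex(cfg)
    for (t in seq_along(progs)) {
        own <- type == paste0("type", t)
        if (any(own)) mu[progs[[t]], own] <- cfg@baselineMean * cfg@programFold
    }
    if (conditionDesign && length(cfg@causalGenes)) {
        ci <- match(cfg@causalGenes, geneIds)
        if (anyNA(ci))
            stop("causal genes absent from the gene universe: ",
                 paste(cfg@causalGenes[is.na(ci)], collapse = ", "))
        b <- condition == "B"
        if (any(b)) mu[ci, b] <- mu[ci, b] * cfg@causalFold
    }

    counts <- if (n > 0L && cfg@nGenes > 0L) .sampleCounts(mu, cfg@dispersion)
              else methods::as(Matrix::Matrix(0L, cfg@nGenes, n, sparse = TRUE),
                               "CsparseMatrix")
    dimnames(counts) <- list(geneIds, cellIds)
    meta <- S4Vectors::DataFrame(dataset_id = rep("synthetic", n),
                                 cell_type = type, condition = condition,
                                 row.names = cellIds)
    dataset <- .buildDataset(counts, geneIds, mito, meta)
    truth <- methods::new("PlantedTruth",
        cellType = stats::setNames(type, cellIds),
        condition = stats::setNames(condition, cellIds),
        qcViolations = list(), causalGenes = cfg@causalGenes)
    list(dataset = dataset, truth = truth)
}

#' Generate a synthetic corpus with planted cell-type programs
#'
#' @param config a [SyntheticConfig]
#' @return a list with `dataset` (a [RankCellDataset]) and `truth`
#'   (a [PlantedTruth] carrying the per-cell type labels)
#' @examples
#' sim <- simulateCorpus(syntheticConfig(nCells = 50, nGenes = 100, seed = 1))
#' dim(sim$dataset)
#' @export
simulateCorpus <- function(config) {
    methods::validObject(config)
    .simulate(config, conditionDesign = FALSE)
}

#' Generate a matched two-condition dataset with planted causal genes
#'
#' Cells alternate between condition A and condition B; condition-B cells
#' draw the configured causal genes with their mean multiplied by
#' `causalFold` while all other structure (cell-type programs, noise) is
#' shared. With `causalFold = 1` the two conditions are statistically
#' exchangeable.
#'
#' @param config a [SyntheticConfig] with `nConditions = 2` and non-empty
#'   `causalGenes`
#' @return list with `dataset` and `truth` (condition labels, causal genes)
#' @export
simulateConditionPair <- function(config) {
    methods::validObject(config)
    if (config@nConditions != 2L)
        stop("generateConditionPair requires nConditions = 2")
    if (!length(config@causalGenes))
        stop("causalGenes must be non-empty for a condition pair")
    .simulate(config, conditionDesign = TRUE)
}

# evaluate the four QC predicates with plain arithmetic (generator-side
# bookkeeping, independent of the corpus_qc implementation under test)
.firedFilters <- function(total, mitoTotal, detected, thresholds) {
    mT <- mean(total); sT <- sqrt(mean((total - mT)^2))
    mM <- mean(mitoTotal); sM <- sqrt(mean((mitoTotal - mM)^2))
    k <- thresholds@sdMultiplier
    dev <- function(x, m, s) if (thresholds@twoSided) abs(x - m) > k * s
                             else x - m > k * s
    list(sd_total = dev(total, mT, sT),
         sd_mito = dev(mitoTotal, mM, sM),
         min_genes = detected < thresholds@minGenesPerCell,
         max_total = total > thresholds@maxTotalCounts)
}

#' Append cells engineered to violate specific QC filters
#'
#' Appends, for each requested filter, cells constructed to trip it:
#' `min_genes` cells detect at most `minGenesPerCell - 1` genes while
#' keeping a typical total; `max_total` cells exceed the absolute count cap;
#' `sd_total` / `sd_mito` cells sit far outside the 3-SD band of the clean
#' population's totals / mitochondrial totals. Because the band filters are
#' relative, an engineered extreme may trip more than one predicate (a
#' `max_total` cell is usually also a total-count outlier); the returned
#' truth annotates every cell with exactly the set of filters it violates,
#' evaluated on the combined dataset.
#'
#' @param dataset a clean [RankCellDataset]
#' @param violations named integer vector with any of `sd_total`,
#'   `sd_mito`, `min_genes`, `max_total` giving how many violating cells to
#'   append (all zero leaves the dataset untouched)
#' @param seed integer seed for the violators' count noise
#' @param thresholds the [QCThresholds] the violations are aimed at
#' @return list with `dataset` (clean + appended cells) and `truth` (a
#'   [PlantedTruth] whose `qcViolations` maps each violating cell to the
#'   filters it trips)
#' @export
plantQCViolations <- function(dataset,
                              violations = c(sd_total = 0L, sd_mito = 0L,
                                             min_genes = 0L, max_total = 0L),
                              seed = 1L,
                              thresholds = methods::new("QCThresholds")) {
    known <- c("sd_total", "sd_mito", "min_genes", "max_total")
    if (!all(names(violations) %in% known))
        stop("unknown filter name(s): ",
             paste(setdiff(names(violations), known), collapse = ", "))
    req <- stats::setNames(rep(0L, 4), known)
    req[names(violations)] <- as.integer(violations)

    counts <- SummarizedExperiment::assay(dataset, "counts")
    mito <- SummarizedExperiment::rowData(dataset)$mito
    if (sum(req) == 0L) {
        truth <- methods::new("PlantedTruth",
            cellType = character(), condition = character(),
            qcViolations = list(), causalGenes = character())
        return(list(dataset = dataset, truth = truth))
    }
    if (ncol(counts) == 0L || nrow(counts) < thresholds@minGenesPerCell)
        stop("clean dataset too small to engineer the requested violations")

    set.seed(seed)
    total <- Matrix::colSums(counts)
    mitoTotal <- Matrix::colSums(counts[mito, , drop = FALSE])
    mT <- mean(total); sT <- stats::sd(total)
    mM <- mean(mitoTotal)
    sM <- stats::sd(mitoTotal)
    nonMitoIdx <- which(!mito)
    mitoIdx <- which(mito)
    if (!length(nonMitoIdx))
        stop("cannot engineer violations: no non-mitochondrial genes")

    # profile helper: spread `tot` counts over k non-mito genes, plus a
    # typical mitochondrial load so the mito filter stays quiet
    mkCell <- function(tot, kGenes, mitoLoad) {
        v <- numeric(nrow(counts))
        kGenes <- min(kGenes, length(nonMitoIdx))
        g <- nonMitoIdx[seq_len(kGenes)]
        base <- tot %/% kGenes
        v[g] <- base
        v[g[1]] <- v[g[1]] + tot - base * kGenes
        if (length(mitoIdx) && mitoLoad > 0) {
            mb <- mitoLoad %/% length(mitoIdx)
            v[mitoIdx] <- mb
            v[mitoIdx[1]] <- v[mitoIdx[1]] + mitoLoad - mb * length(mitoIdx)
        }
        v
    }
    typicalMito <- round(mM)
    if (req["sd_mito"] > 0L && !length(mitoIdx))
        stop("sd_mito violation unachievable: no mitochondrial genes")

    # because the band filters are relative and the appended extremes
    # inflate the combined mean/SD themselves, violator magnitudes are
    # grown iteratively until every engineered cell trips its own filter
    # against the statistics of the combined dataset
    totMag <- rep(round(mT + 8 * max(sT, 1) + 50), req["sd_total"])
    mitoMag <- rep(round(mM + 8 * max(sM, 1) + 20), req["sd_mito"])
    combined <- NULL
    bad <- list()
    for (iter in seq_len(30L)) {
        bad <- list()
        addBad <- function(name, v) {
            i <- length(bad) + 1L
            bad[[i]] <<- v
            names(bad)[i] <<- sprintf("bad_%s_%03d", name, i)
        }
        for (i in seq_len(req["sd_total"]))
            addBad("sd_total", mkCell(totMag[i] + i, 50L, typicalMito))
        for (i in seq_len(req["sd_mito"])) {
            v <- mkCell(round(max(mT - typicalMito, 20)), 50L, 0)
            v[mitoIdx[1]] <- mitoMag[i] + i
            addBad("sd_mito", v)
        }
        for (i in seq_len(req["min_genes"]))
            addBad("min_genes",
                   mkCell(round(mT) - typicalMito,
                          thresholds@minGenesPerCell - 2L, typicalMito))
        for (i in seq_len(req["max_total"]))
            addBad("max_total",
                   mkCell(round(thresholds@maxTotalCounts * 1.25) + i, 200L,
                          typicalMito))
        badDense <- do.call(cbind, bad)
        allTot <- c(total, colSums(badDense))
        allMito <- c(mitoTotal, colSums(badDense[mito, , drop = FALSE]))
        k <- thresholds@sdMultiplier
        mTc <- mean(allTot); sTc <- sqrt(mean((allTot - mTc)^2))
        mMc <- mean(allMito); sMc <- sqrt(mean((allMito - mMc)^2))
        okTot <- !req["sd_total"] ||
            all(colSums(badDense)[grep("sd_total", names(bad))] >
                mTc + k * sTc)
        okMito <- !req["sd_mito"] ||
            all(colSums(badDense[mito, grep("sd_mito", names(bad)),
                                 drop = FALSE]) > mMc + k * sMc)
        if (okTot && okMito) break
        if (!okTot) totMag <- round(pmax(totMag * 2, mTc + (k + 2) * sTc))
        if (!okMito) mitoMag <- round(pmax(mitoMag * 2,
                                           mMc + (k + 2) * sMc))
        if (iter == 30L)
            stop("requested SD-band violations unachievable given the ",
                 "clean-population statistics")
    }

    badMat <- methods::as(Matrix::Matrix(do.call(cbind, bad), sparse = TRUE),
                          "CsparseMatrix")
    colnames(badMat) <- names(bad)
    rownames(badMat) <- rownames(counts)
    combined <- cbind(counts, badMat)

    oldMeta <- SummarizedExperiment::colData(dataset)
    badMeta <- oldMeta[rep(NA_integer_, length(bad)), , drop = FALSE]
    rownames(badMeta) <- names(bad)
    if ("dataset_id" %in% colnames(badMeta))
        badMeta$dataset_id <- rep(oldMeta$dataset_id[1] %||% "synthetic",
                                  length(bad))
    meta <- rbind(oldMeta, badMeta)

    out <- .buildDataset(combined, rownames(counts), mito, meta)

    fired <- .firedFilters(Matrix::colSums(combined),
                           Matrix::colSums(combined[mito, , drop = FALSE]),
                           Matrix::colSums(combined > 0), thresholds)
    anyFired <- Reduce(`|`, fired)
    viol <- lapply(which(anyFired), function(j)
        names(fired)[vapply(fired, `[`, logical(1), j)])
    names(viol) <- colnames(combined)[anyFired]

    for (nm in names(bad)) {
        want <- sub("^bad_([a-z_]+)_\\d+$", "\\1", nm)
        if (!nm %in% names(viol) || !want %in% viol[[nm]])
            stop("requested violation '", want, "' unachievable for cell ",
                 nm, " given the clean-population statistics")
    }
    truth <- methods::new("PlantedTruth",
        cellType = character(), condition = character(),
        qcViolations = viol, causalGenes = character())
    list(dataset = out, truth = truth)
}
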