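#' @include AllClasses.R AllGenerics.R
NULL

#' Read the two homology stage tables
#'
#' Stage 1 maps human Ensembl ids through gene symbols to mouse MGI ids
#' (columns `human_ensembl_id`, `gene_symbol`, `mouse_mgi_id`); stage 2
#' maps MGI ids to mouse Ensembl ids (columns `mouse_mgi_id`,
#' `mouse_ensembl_id`). Either stage may be one-to-many. File order is
#' semantically load-bearing for stage 2 — the "final id in the output"
#' tie-break picks the last record — so both readers preserve row order
#' exactly. Ensembl version suffixes are stripped on read.
#'
#' @param path TSV file with a header row
#' @return data.frame in file order
#' @export
readHomologyStage1 <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("human_ensembl_id", "gene_symbol", "mouse_mgi_id")
    if (!all(need %in% colnames(df)))
        stop("stage-1 table must have columns: ", paste(need, collapse = ", "))
    df$human_ensembl_id <- stripEnsemblVersion(df$human_ensembl_id)
    df[need]
}

#' @rdname readHomologyStage1
#' @export
readHomologyStage2 <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("mouse_mgi_id", "mouse_ensembl_id")
    if (!all(need %in% colnames(df)))
        stop("stage-2 table must have columns: ", paste(need, collapse = ", "))
    df$mouse_ensembl_id <- stripEnsemblVersion(df$mouse_ensembl_id)
    df[need]
}

#' Strip Ensembl version suffixes ("ENSMUSG0000001.3" -> "ENSMUSG0000001")
#' @param ids character identifiers
#' @export
stripEnsemblVersion <- function(ids) sub("\\.\\d+$", "", ids)

# alphabetical sort of gene symbols: case-insensitive primary order with a
# case-sensitive tie-break, locale-independent
.sortSymbols <- function(symbols) {
    symbols[order(toupper(symbols), symbols, method = "radix")]
}

#' Resolve homology records to a one-to-one gene mapping
#'
#' Applies the two published tie-break rules. For a human Ensembl id with
#' several (symbol, MGI) candidates, the symbols are sorted alphabetically
#' and the last symbol's MGI id is chosen; for an MGI id with several
#' mouse Ensembl ids, the final id in the stage-2 table's record order is
#' chosen. Human ids whose chosen MGI id has no stage-2 record are
#' unmapped. If, after both rules, two human ids land on the same mouse
#' Ensembl id, only the first (in stage-1 record order) keeps the pair and
#' the rest are unmapped, so the table is injective in both directions.
#' Every applied tie-break is recorded in the provenance table.
#'
#' @param stage1 data.frame from [readHomologyStage1()]
#' @param stage2 data.frame from [readHomologyStage2()]
#' @return an [OrthologTable]
#' @export
resolveOneToOne <- function(stage1, stage2) {
    if (!nrow(stage1)) stop("stage-1 table is empty")
    if (anyDuplicated(stage1) || anyDuplicated(stage2))
        stop("fully duplicated homology records are not allowed")
    humans <- unique(stage1$human_ensembl_id)
    # rule 2 pre-computation: last mouse Ensembl id per MGI in file order
    mgiLast <- tapply(seq_len(nrow(stage2)), stage2$mouse_mgi_id, max)
    rows <- vector("list", length(humans))
    for (i in seq_along(humans)) {
        cand <- stage1[stage1$human_ensembl_id == humans[i], , drop = FALSE]
        tie1 <- nrow(cand) > 1L
        sym <- .sortSymbols(cand$gene_symbol)
        chosen <- sym[length(sym)]
        mgi <- cand$mouse_mgi_id[cand$gene_symbol == chosen]
        mgi <- mgi[length(mgi)]          # same symbol twice: last record
        li <- unname(mgiLast[mgi])
        tie2 <- !is.na(li) && sum(stage2$mouse_mgi_id == mgi) > 1L
        mouse <- if (is.na(li)) NA_character_
                 else stage2$mouse_ensembl_id[li]
        rows[[i]] <- data.frame(
            human_ensembl_id = humans[i], chosen_symbol = chosen,
            chosen_mgi = mgi, mouse_ensembl_id = mouse,
            tie_break = tie1 || isTRUE(tie2),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    unmappedHuman <- res$human_ensembl_id[is.na(res$mouse_ensembl_id)]
    res <- res[!is.na(res$mouse_ensembl_id), , drop = FALSE]
    dup <- duplicated(res$mouse_ensembl_id)
    unmappedHuman <- c(unmappedHuman, res$human_ensembl_id[dup])
    res <- res[!dup, , drop = FALSE]
    unmappedMouse <- setdiff(unique(stage2$mouse_ensembl_id),
                             res$mouse_ensembl_id)
    methods::new("OrthologTable",
        forward = stats::setNames(res$mouse_ensembl_id,
                                  res$human_ensembl_id),
        provenance = S4Vectors::DataFrame(res),
        unmappedHuman = unmappedHuman, unmappedMouse = unmappedMouse)
}

#' Convert a count matrix between species
#'
#' Renames mapped genes to their orthologs and drops unmapped genes; count
#' values are never altered, only the gene axis. A duplicate target
#' identifier (impossible after [resolveOneToOne()]) is an invariant
#' violation and raises an error.
#'
#' @param dataset a [RankCellDataset]
#' @param table an [OrthologTable]
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`
#' @return list with `dataset` (converted) and `report` (mapped/dropped
#'   counts and the dropped identifiers)
#' @export
convertMatrix <- function(dataset, table,
                          direction = c("human_to_mouse",
                                        "mouse_to_human")) {
    direction <- match.arg(direction)
    map <- if (direction == "human_to_mouse") forwardMap(table)
           else reverseMap(table)
    genes <- rownames(dataset)
    target <- unname(map[genes])
    keep <- !is.na(target)
    if (anyDuplicated(target[keep]))
        stop("duplicate target identifiers after conversion: ",
             paste(utils::head(unique(target[keep][
                 duplicated(target[keep])]), 5), collapse = ", "))
    out <- dataset[keep, ]
    rownames(out) <- target[keep]
    report <- list(n_mapped = sum(keep), n_dropped = sum(!keep),
                   dropped = genes[!keep], direction = direction)
    list(dataset = out, report = report)
}
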