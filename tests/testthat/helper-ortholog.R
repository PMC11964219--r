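# independent brute-force resolver: literal application of the two rules
# (sort symbols, take the last; take the final stage-2 record), then first-
# come-first-kept de-duplication of mouse targets in stage-1 order
.bruteResolve <- function(stage1, stage2) {
    out <- character()
    for (h in unique(stage1$human_ensembl_id)) {
        cand <- stage1[stage1$human_ensembl_id == h, ]
        syms <- cand$gene_symbol[order(toupper(cand$gene_symbol),
                                       cand$gene_symbol, method = "radix")]
        sym <- syms[length(syms)]
        mgis <- cand$mouse_mgi_id[cand$gene_symbol == sym]
        mgi <- mgis[length(mgis)]
        hits <- stage2$mouse_ensembl_id[stage2$mouse_mgi_id == mgi]
        if (!length(hits)) next
        mouse <- hits[length(hits)]
        if (!(mouse %in% out)) out[h] <- mouse
    }
    out
}

.randRecords <- function(seed) {
    set.seed(seed)
    nH <- 100L
    humans <- sprintf("ENSG%011d", sample(1e6, nH))
    syms <- replicate(nH + 40, paste0(sample(c(LETTERS, letters), 4),
                                      collapse = ""))
    mgis <- sprintf("MGI:%06d", sample(1e6, 80))
    s1 <- do.call(rbind, lapply(seq_len(nH), function(i) {
        k <- sample(c(1L, 1L, 1L, 2L, 3L), 1)    # injected multiplicities
        data.frame(human_ensembl_id = humans[i],
                   gene_symbol = sample(syms, k),
                   mouse_mgi_id = sample(mgis, k, replace = TRUE))
    }))
    s2 <- do.call(rbind, lapply(unique(s1$mouse_mgi_id), function(mg) {
        k <- sample(c(1L, 1L, 2L), 1)
        data.frame(mouse_mgi_id = mg,
                   mouse_ensembl_id = sprintf("ENSMUSG%011d",
                                              sample(1e6, k)))
    }))
    s2 <- s2[sample(nrow(s2)), ]
    rownames(s2) <- NULL
    list(s1 = unique(s1), s2 = unique(s2))
}

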