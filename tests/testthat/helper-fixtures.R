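# shared builders for toy objects used across test files

# dge_matrix from a dense integer matrix (genes x cells)
toy_dge <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("cell%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  counts <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  nerveLR:::new_dge(counts)
}

toy_annot <- function(cell_ids, cell_types, datasets = "d1") {
  data.frame(cell_id = cell_ids, cell_type = cell_types,
             dataset = rep_len(datasets, length(cell_ids)))
}

toy_db <- function(pairs) {
  lr_db(data.frame(ligand = vapply(pairs, `[`, "", 1L),
                   receptor = vapply(pairs, `[`, "", 2L)))
}

# exact two-sided 99% binomial acceptance interval for a proportion
binom99 <- function(n, p) {
  stats::qbinom(c(0.005, 0.995), n, p) / n
}

# tie-break vector for the injured-nerve table, derived from the table's own
# per-ligand annotation (computed from unrounded fractions by the source)
table2_tie_break <- function(tab, assignment, members) {
  mark <- attr(tab, "marker")
  tied <- assignment$gene[assignment$tie]
  vapply(tied, function(g) {
    leaders <- strsplit(assignment$top_types[assignment$gene == g], ",")[[1L]]
    memb <- intersect(leaders, members)
    oth <- setdiff(leaders, members)
    if (identical(mark[[g]], "**")) memb[1L] else oth[1L]
  }, "")
}

injured_compare_types <- c("epineurial_perineurial", "endoneurial",
                           "vsm_pericytes", "endothelial", "schwann",
                           "immune")
mesenchymal_members <- c("epineurial_perineurial", "endoneurial")
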