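# internal: library-size normalization + log1p, returning a dense matrix
# over the selected genes. "none" leaves raw counts (still log-free).
normalize_counts <- function(counts, normalization = c("library-size", "none"),
                             genes = NULL) {
  normalization <- match.arg(normalization)
  if (!is.null(genes)) {
    genes <- intersect(norm_genes(genes), rownames(counts))
    if (length(genes) < 2L) stop("fewer than 2 genes in scope", call. = FALSE)
  } else {
    genes <- rownames(counts)
  }
  m <- as.matrix(counts[genes, , drop = FALSE])
  if (normalization == "library-size") {
    libs <- Matrix::colSums(counts)
    if (any(libs == 0)) stop("cell(s) with zero total counts", call. = FALSE)
    scale <- libs / stats::median(libs)
    m <- log1p(sweep(m, 2L, scale, `/`))
  }
  m
}

#' Mock bulk transcriptome of a dataset
#'
#' The pseudobulk reference profile of a dataset: the per-gene arithmetic
#' mean of (optionally library-size-normalized, log1p-transformed)
#' expression over all its cells. Single cells are later correlated against
#' these profiles on the same normalization.
#'
#' @param dge a `dge_matrix`.
#' @param annot cell annotations with `cell_id` and `dataset`.
#' @param dataset dataset label selecting the member cells (>= 1 cell).
#' @param normalization `"library-size"` (default; normalization factors are
#'   computed over all cells in the matrix) or `"none"`.
#' @return object of class `mock_bulk`: list with `name` and `profile`
#'   (named per-gene means).
#' @export
mock_bulk <- function(dge, annot, dataset,
                      normalization = c("library-size", "none")) {
  normalization <- match.arg(normalization)
  cells <- annot$cell_id[annot$dataset == dataset]
  if (!length(cells)) stop("empty dataset: ", dataset, call. = FALSE)
  m <- normalize_counts(dge$counts, normalization)
  structure(list(name = dataset,
                 profile = rowMeans(m[, cells, drop = FALSE])),
            class = "mock_bulk")
}

#' Correlate single cells with mock bulk profiles
#'
#' Pearson correlation of every cell's (normalized) expression vector with
#' each mock bulk profile, over the shared gene set. Cells with zero
#' variance over the genes in scope have no defined correlation; they are
#' excluded and reported in the `flagged_cells` attribute.
#'
#' @param dge a `dge_matrix`.
#' @param bulks list of `mock_bulk` objects.
#' @param gene_subset optional gene set restricting the correlation (e.g.
#'   highly variable genes); default all shared genes.
#' @param normalization must match the normalization used for the bulks.
#' @return numeric matrix, cells x bulks, of Pearson r in \[-1, 1\], with
#'   attribute `flagged_cells`.
#' @export
correlate_cells <- function(dge, bulks,
                            gene_subset = NULL,
                            normalization = c("library-size", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(length(bulks) >= 1, all(vapply(bulks, inherits, TRUE, "mock_bulk")))
  genes <- Reduce(intersect, c(list(rownames(dge$counts)),
                               lapply(bulks, function(b) names(b$profile))))
  if (!is.null(gene_subset)) genes <- intersect(genes, norm_genes(gene_subset))
  if (length(genes) < 2L) stop("fewer than 2 genes in scope", call. = FALSE)
  m <- normalize_counts(dge$counts, normalization, genes = genes)
  bp <- vapply(bulks, function(b) b$profile[genes], numeric(length(genes)))
  colnames(bp) <- vapply(bulks, `[[`, "", "name")
  if (any(apply(bp, 2L, stats::sd) == 0)) {
    stop("constant mock bulk profile", call. = FALSE)
  }
  sds <- apply(m, 2L, stats::sd)
  flagged <- colnames(m)[sds == 0]
  if (length(flagged)) {
    warning(length(flagged), " zero-variance cell(s) excluded", call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(m, bp)
  attr(r, "flagged_cells") <- flagged
  r
}

#' Differential-correlation coordinates for single cells
#'
#' Places each cell in a 2D plane whose axes are differences of Pearson
#' correlations with two pairs of mock bulk references: `x = r(cell, A) -
#' r(cell, B)` for the x-axis pair, and likewise for the y-axis pair.
#' Positive x means the cell is more similar to the first (minuend) profile
#' of the pair. Coordinates lie in \[-2, 2\].
#'
#' @param r correlation matrix from [correlate_cells()].
#' @param x_pair,y_pair character vectors of two bulk names each
#'   `(minuend, subtrahend)`.
#' @return data.frame with `cell_id`, `x`, `y` and the four retained r
#'   columns.
#' @export
differential_coordinates <- function(r, x_pair, y_pair) {
  stopifnot(length(x_pair) == 2L, length(y_pair) == 2L)
  need <- unique(c(x_pair, y_pair))
  miss <- setdiff(need, colnames(r))
  if (length(miss)) stop("unknown bulk profile(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(cell_id = rownames(r),
                    x = r[, x_pair[1L]] - r[, x_pair[2L]],
                    y = r[, y_pair[1L]] - r[, y_pair[2L]],
                    row.names = NULL)
  for (nm in need) out[[paste0("r_", nm)]] <- r[, nm]
  out
}
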