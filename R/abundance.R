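#' Construct a detection table
#'
#' A detection table holds, for each gene and cell type, the percentage of
#' cells of that type with detectable expression (UMI count >= 1). Tables
#' computed from count matrices have exact fractions everywhere; tables
#' transcribed from printed sources may carry `NA` where only "below
#' threshold" (< 2% of cells) is known.
#'
#' @param fraction numeric matrix, genes x cell types, values in \[0, 100\] or
#'   `NA`.
#' @param n_cells optional named vector of per-cell-type cell totals.
#' @param below optional logical matrix marking entries reported as below
#'   threshold; defaults to `is.na(fraction) | fraction < 2`.
#' @return object of class `detection_table`.
#' @export
detection_table <- function(fraction, n_cells = NULL, below = NULL) {
  stopifnot(is.matrix(fraction))
  if (any(fraction < 0 | fraction > 100, na.rm = TRUE)) {
    stop("detection fractions must lie in [0, 100]", call. = FALSE)
  }
  rownames(fraction) <- norm_genes(rownames(fraction))
  if (is.null(below)) below <- is.na(fraction) | fraction < 2
  if (!is.null(n_cells)) {
    n_cells <- n_cells[colnames(fraction)]
  }
  structure(list(fraction = fraction, n_cells = n_cells, below = below),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("<detection_table: %d genes x %d cell types>\n",
              nrow(x$fraction), ncol(x$fraction)))
  invisible(x)
}

#' Per-cell-type detection fractions
#'
#' The core single-cell statistic: for every gene and cell type, the
#' percentage of cells of that type in which the gene is detectably expressed.
#' A cell detectably expresses a gene iff its raw UMI count is >= 1; no
#' normalization is applied.
#'
#' @param dge a `dge_matrix` (see [read_dge()]).
#' @param annot cell annotation data.frame with `cell_id` and `cell_type`;
#'   every annotated cell must be present in the matrix.
#' @param genes optional gene set restricting the rows; genes absent from the
#'   matrix get fraction 0 with a warning.
#' @return `detection_table` with exact fractions and per-type cell counts.
#' @export
detection_fractions <- function(dge, annot, genes = NULL) {
  counts <- dge$counts
  missing_cells <- setdiff(annot$cell_id, colnames(counts))
  if (length(missing_cells)) {
    stop("annotated cell(s) absent from matrix: ",
         paste(utils::head(missing_cells, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- rownames(counts)
  } else {
    genes <- unique(norm_genes(genes))
  }
  absent <- setdiff(genes, rownames(counts))
  if (length(absent)) {
    warning("gene(s) absent from matrix, reported as fraction 0: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  types <- sort(unique(annot$cell_type))
  present <- intersect(genes, rownames(counts))
  detected <- counts[present, , drop = FALSE] >= 1
  frac <- matrix(0, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
  n_cells <- stats::setNames(integer(length(types)), types)
  for (t in types) {
    cells <- annot$cell_id[annot$cell_type == t]
    n_cells[t] <- length(cells)
    if (length(present)) {
      frac[present, t] <-
        100 * Matrix::rowSums(detected[, cells, drop = FALSE]) / length(cells)
    }
  }
  detection_table(frac, n_cells = n_cells)
}

#' Expressed gene sets at a detection threshold
#'
#' A gene counts as expressed in a cell type when its detection fraction is at
#' or above `threshold` percent (inclusive; printed tables list 2.0 as
#' expressed). Entries known only as "below threshold" never qualify.
#'
#' @param table a `detection_table`.
#' @param threshold percent of cells, in (0, 100\]; default 2.
#' @return named list with one `gene_set` per cell type plus `any_type`, the
#'   union over all cell types.
#' @export
expressed_sets <- function(table, threshold = 2) {
  stopifnot(inherits(table, "detection_table"))
  if (!(threshold > 0 && threshold <= 100)) {
    stop("threshold must lie in (0, 100]", call. = FALSE)
  }
  f <- table$fraction
  ok <- !is.na(f) & f >= threshold
  sets <- lapply(colnames(f), function(t) {
    gene_set(rownames(f)[ok[, t]], name = t)
  })
  names(sets) <- colnames(f)
  sets$any_type <- gene_set(rownames(f)[rowSums(ok) > 0], name = "any_type")
  sets
}

#' Assign each gene to its highest-expressing cell type
#'
#' Uses strict maximum over the compared cell types; genes whose top fraction
#' is shared by several types are flagged as ties and, unless `tie_break`
#' resolves them, left unassigned. Below-threshold entries rank below every
#' numeric fraction. Aggregate columns (e.g. a combined-mesenchymal column)
#' should be excluded via `compare_types`.
#'
#' @param table a `detection_table`.
#' @param compare_types cell types to compare; defaults to all columns.
#' @param mesenchymal_members optional subset of `compare_types`; when given,
#'   the result gains a logical `group_highest` column that is `TRUE` when the
#'   maximum over the members strictly exceeds every non-member fraction.
#' @param tie_break optional named character vector, gene -> cell type, used
#'   to resolve exact ties (e.g. from an external annotation of the same
#'   data at higher precision).
#' @return data.frame with columns `gene`, `assigned` (NA for unresolved
#'   ties), `top_types` (comma-joined tied leaders), `tie`, `max_fraction`,
#'   and `group_highest` when `mesenchymal_members` is given. Genes with no
#'   expression anywhere get `assigned = NA` and `tie = FALSE`.
#' @export
assign_highest <- function(table, compare_types = NULL,
                           mesenchymal_members = NULL, tie_break = NULL) {
  stopifnot(inherits(table, "detection_table"))
  f <- table$fraction
  if (is.null(compare_types)) compare_types <- colnames(f)
  miss <- setdiff(compare_types, colnames(f))
  if (length(miss)) stop("unknown cell type(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  v <- f[, compare_types, drop = FALSE]
  v[is.na(v)] <- -Inf
  top <- apply(v, 1L, max)
  res <- data.frame(gene = rownames(f), assigned = NA_character_,
                    top_types = NA_character_, tie = FALSE,
                    max_fraction = ifelse(is.finite(top), top, NA_real_),
                    row.names = NULL)
  for (i in seq_len(nrow(v))) {
    if (!is.finite(top[i]) || top[i] <= 0) next
    leaders <- compare_types[v[i, ] == top[i]]
    res$top_types[i] <- paste(leaders, collapse = ",")
    if (length(leaders) == 1L) {
      res$assigned[i] <- leaders
    } else {
      res$tie[i] <- TRUE
      tb <- tie_break[res$gene[i]]
      if (!is.null(tie_break) && !is.na(tb) && tb %in% leaders) {
        res$assigned[i] <- unname(tb)
      }
    }
  }
  if (!is.null(mesenchymal_members)) {
    members <- intersect(mesenchymal_members, compare_types)
    others <- setdiff(compare_types, members)
    mmax <- apply(v[, members, drop = FALSE], 1L, max)
    omax <- apply(v[, others, drop = FALSE], 1L, max)
    res$group_highest <- is.finite(mmax) & mmax > 0 & mmax > omax
    # resolved ties count with the side the tie-break chose
    tied <- which(res$tie & !is.na(res$assigned))
    if (length(tied)) {
      res$group_highest[tied] <- res$assigned[tied] %in% members
    }
  }
  res
}

#' Pooled detection fraction over merged cell types
#'
#' The detection fraction of a combined population is computed over the pooled
#' cells of all member types (weighted by cell counts), not as the mean of the
#' member fractions.
#'
#' @param table a `detection_table` with known `n_cells`.
#' @param member_types cell types to pool.
#' @return named numeric vector, one pooled percentage per gene.
#' @export
combined_fraction <- function(table, member_types) {
  stopifnot(inherits(table, "detection_table"))
  if (is.null(table$n_cells)) {
    stop("combined_fraction needs per-cell-type cell counts", call. = FALSE)
  }
  miss <- setdiff(member_types, colnames(table$fraction))
  if (length(miss)) stop("unknown cell type(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n <- table$n_cells[member_types]
  f <- table$fraction[, member_types, drop = FALSE]
  if (anyNA(f)) stop("cannot pool below-threshold entries with unknown value",
                     call. = FALSE)
  stats::setNames(as.vector(f %*% n) / sum(n), rownames(f))
}

#' Fold changes between two detection-fraction columns
#'
#' Ratios are taken on the raw (unrounded) fractions, including fractions
#' below the 2% reporting threshold. A zero denominator with a positive
#' numerator yields a lower-bound marker `">numerator"`; zero over zero is
#' undefined and shown as `"-"`.
#'
#' @param numerator,denominator named numeric vectors of percentages over the
#'   same genes (names are matched; order free).
#' @return data.frame with columns `gene`, `numerator`, `denominator`,
#'   `ratio` (NA when not a plain ratio) and `display` (printed form, using
#'   the lower-bound / undefined markers).
#' @export
fold_changes <- function(numerator, denominator) {
  genes <- names(numerator)
  if (is.null(genes) || is.null(names(denominator))) {
    stop("numerator and denominator must be named by gene", call. = FALSE)
  }
  if (!setequal(genes, names(denominator))) {
    stop("numerator and denominator cover different gene panels", call. = FALSE)
  }
  den <- denominator[genes]
  ratio <- ifelse(den > 0, numerator / den, NA_real_)
  display <- ifelse(den > 0, formatC(ratio, format = "fg"),
                    ifelse(numerator > 0,
                           paste0(">", formatC(numerator, format = "fg")), "-"))
  data.frame(gene = genes, numerator = unname(numerator),
             denominator = unname(den), ratio = unname(ratio),
             display = unname(display), row.names = NULL)
}

#' Flag genes enriched in one cell type
#'
#' A gene is flagged when its detection fraction in the focal type is at least
#' `factor` times the maximum fraction over all other compared types (and
#' positive). Below-threshold entries in fixture tables are treated as zero.
#'
#' @param table a `detection_table`.
#' @param focal_type the cell type tested for enrichment.
#' @param factor fold enrichment required; default 4.
#' @param compare_types columns compared against; defaults to all columns
#'   except `focal_type`.
#' @return `gene_set` of flagged genes.
#' @export
enrichment_flags <- function(table, focal_type, factor = 4,
                             compare_types = NULL) {
  stopifnot(inherits(table, "detection_table"))
  f <- table$fraction
  if (!focal_type %in% colnames(f)) {
    stop("unknown focal type: ", focal_type, call. = FALSE)
  }
  if (is.null(compare_types)) compare_types <- setdiff(colnames(f), focal_type)
  v <- f
  v[is.na(v)] <- 0
  focal <- v[, focal_type]
  other <- apply(v[, compare_types, drop = FALSE], 1L, max)
  gene_set(rownames(f)[focal > 0 & focal >= factor * other],
           name = paste0(focal_type, "_enriched"))
}

#' Set algebra over expressed-ligand sets from several datasets
#'
#' Computes the disjoint Venn regions over the per-dataset expressed unions
#' and, when one dataset is designated as the injured condition, the genes
#' expressed only there.
#'
#' @param sets named list of 2 or 3 character vectors (per-dataset expressed
#'   unions).
#' @param injured optional name of the injured dataset in `sets`.
#' @return list with `regions` (see [venn_counts()]) and, when `injured` is
#'   given, `injured_only`, the `gene_set` private to the injured dataset.
#' @export
cross_dataset_sets <- function(sets, injured = NULL) {
  vc <- venn_counts(sets)
  out <- list(regions = vc)
  if (!is.null(injured)) {
    if (!injured %in% names(sets)) stop("unknown dataset: ", injured,
                                        call. = FALSE)
    rest <- Reduce(union, sets[setdiff(names(sets), injured)])
    out$injured_only <- gene_set(setdiff(norm_genes(sets[[injured]]),
                                         norm_genes(rest)),
                                 name = paste0(injured, "_only"))
  }
  out
}
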