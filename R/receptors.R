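#' Summarize probe-level microarray data to gene level
#'
#' Replicate intensities are averaged per probe first; when several probes map
#' to the same gene, the highest-expressed probe (after averaging) represents
#' the gene. Probes without a gene annotation are dropped with a warning.
#'
#' @param probes data.frame with columns `probe`, `gene`, followed by one or
#'   more numeric replicate columns.
#' @param condition name for the resulting expression column.
#' @param units declared unit of the values.
#' @return single-condition `bulk_profile`.
#' @export
summarize_probe_level <- function(probes, condition = "expr",
                                  units = "log2") {
  stopifnot(is.data.frame(probes), all(c("probe", "gene") %in% names(probes)))
  repcols <- setdiff(names(probes), c("probe", "gene"))
  if (!length(repcols)) stop("no replicate columns", call. = FALSE)
  unannotated <- is.na(probes$gene) | !nzchar(trimws(probes$gene))
  if (any(unannotated)) {
    warning(sum(unannotated), " probe(s) without gene annotation dropped",
            call. = FALSE)
    probes <- probes[!unannotated, , drop = FALSE]
  }
  check_unique(probes$probe, "probe")
  probe_mean <- rowMeans(as.matrix(probes[, repcols, drop = FALSE]))
  gene <- norm_genes(probes$gene)
  gene_val <- tapply(probe_mean, gene, max)
  m <- matrix(as.numeric(gene_val), ncol = 1,
              dimnames = list(names(gene_val), condition))
  bulk_profile(m, units = units)
}

# internal receptor_call constructor
new_receptor_call <- function(population, mode, receptors, cutoff_gene = NA,
                              cutoff_value = NA, anchor_percentile = NA,
                              proteome_receptors = NULL) {
  structure(list(population = population, mode = mode,
                 cutoff_gene = cutoff_gene, cutoff_value = cutoff_value,
                 anchor_percentile = anchor_percentile,
                 receptors = receptors,
                 proteome_receptors = proteome_receptors),
            class = "receptor_call")
}

#' @export
print.receptor_call <- function(x, ...) {
  cat(sprintf("<receptor_call '%s' (%s): %d receptors", x$population, x$mode,
              length(x$receptors)))
  if (!is.na(x$cutoff_gene)) cat(", anchor ", x$cutoff_gene, sep = "")
  cat(">\n")
  invisible(x)
}

#' Proteomics-anchored receptor call
#'
#' Defines a neuron population's receptor repertoire from its transcriptome,
#' anchored by cell-surface proteomics: the expression cutoff is the
#' mass-spectrometry-detected receptor with the lowest mRNA expression, and
#' every panel receptor expressed at or above that cutoff (ties included) is
#' called.
#'
#' @param expr `bulk_profile` for the population.
#' @param condition condition column in `expr`.
#' @param population population label (e.g. `"DRG"`, `"SCG"`).
#' @param detected_proteins gene symbols detected at the protein level.
#' @param receptor_panel candidate receptor symbols.
#' @return `receptor_call` with `mode = "anchor"`; `anchor_percentile` is the
#'   percentage of all profiled genes expressed at or below the cutoff gene.
#' @export
anchor_receptor_call <- function(expr, condition = colnames(expr)[1L],
                                 population, detected_proteins,
                                 receptor_panel) {
  detected <- norm_genes(detected_proteins)
  panel <- unique(norm_genes(receptor_panel))
  vals <- expr[, condition]
  anchors <- intersect(detected, rownames(expr))
  if (!length(anchors)) {
    stop("no mass-spectrometry receptor found in the expression table",
         call. = FALSE)
  }
  cutoff_gene <- anchors[which.min(vals[anchors])]
  cutoff <- vals[[cutoff_gene]]
  present <- intersect(panel, rownames(expr))
  receptors <- gene_set(c(present[vals[present] >= cutoff], cutoff_gene),
                        name = population)
  new_receptor_call(population, "anchor", receptors,
                    cutoff_gene = cutoff_gene, cutoff_value = unname(cutoff),
                    anchor_percentile = 100 * sum(vals <= cutoff) / length(vals),
                    proteome_receptors = gene_set(detected,
                                                  name = "proteome"))
}

#' Percentile-based receptor call
#'
#' Calls the panel receptors whose expression falls within the top
#' `percentile` percent of all profiled genes (at-or-above the cutoff order
#' statistic; ties at the cutoff value are included).
#'
#' @param expr `bulk_profile`.
#' @param condition condition column.
#' @param population population label.
#' @param percentile top share of genes retained, in (0, 100\].
#' @param receptor_panel candidate receptor symbols.
#' @return `receptor_call` with `mode = "percentile"`.
#' @export
percentile_receptor_call <- function(expr, condition = colnames(expr)[1L],
                                     population, percentile, receptor_panel) {
  if (!(percentile > 0 && percentile <= 100)) {
    stop("percentile must lie in (0, 100]", call. = FALSE)
  }
  panel <- unique(norm_genes(receptor_panel))
  vals <- expr[, condition]
  k <- max(1L, round(length(vals) * percentile / 100))
  cutoff <- sort(vals, decreasing = TRUE)[k]
  present <- intersect(panel, rownames(expr))
  receptors <- gene_set(present[vals[present] >= cutoff], name = population)
  new_receptor_call(population, "percentile", receptors,
                    cutoff_value = unname(cutoff),
                    anchor_percentile = 100 - percentile)
}

#' FPKM-threshold receptor call
#'
#' For RNA-seq profiles in FPKM units: panel receptors with FPKM strictly
#' greater than `min_fpkm` are called expressed.
#'
#' @param expr `bulk_profile` declared in FPKM units.
#' @param condition condition column.
#' @param population population label.
#' @param min_fpkm threshold; default 1.
#' @param receptor_panel candidate receptor symbols.
#' @return `receptor_call` with `mode = "fpkm"`.
#' @export
fpkm_receptor_call <- function(expr, condition = colnames(expr)[1L],
                               population, min_fpkm = 1, receptor_panel) {
  if (!identical(attr(expr, "units"), "fpkm")) {
    stop("expression profile must be declared in FPKM units", call. = FALSE)
  }
  panel <- unique(norm_genes(receptor_panel))
  vals <- expr[, condition]
  present <- intersect(panel, rownames(expr))
  receptors <- gene_set(present[vals[present] > min_fpkm], name = population)
  new_receptor_call(population, "fpkm", receptors, cutoff_value = min_fpkm)
}

#' Count receptors per functional class
#'
#' @param receptors receptor symbols (or a `receptor_call`).
#' @param class_map named character vector, gene symbol -> class label
#'   (user-supplied, e.g. from GO terms). Unmapped receptors are counted
#'   under `"unclassified"`.
#' @return named integer vector of class counts.
#' @export
classify_receptors <- function(receptors, class_map) {
  if (inherits(receptors, "receptor_call")) receptors <- receptors$receptors
  receptors <- unique(norm_genes(receptors))
  names(class_map) <- norm_genes(names(class_map))
  cls <- class_map[receptors]
  cls[is.na(cls)] <- "unclassified"
  counts <- table(cls)
  stats::setNames(as.integer(counts), names(counts))
}
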