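# Accessors for the bundled reference tables: ligand and receptor lists and
# per-cell-type detection fractions transcribed from the printed supplementary
# tables of the nerve interactome study. Below-threshold entries ("BT", i.e.
# detected in < 2% of cells) are kept as a distinct token; where the source
# prints a parenthetical raw value next to BT, that value is retained.

#' Path to a bundled fixture file
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
nerve_fixture <- function(file) {
  p <- system.file("extdata", file, package = "nerveLR", mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled fixture: ", file, call. = FALSE)
  p
}

# internal: raw fixture read
read_fixture <- function(file) {
  utils::read.delim(nerve_fixture(file), check.names = FALSE,
                    colClasses = "character")
}

# internal: parse printed detection tokens ("BT", "BT (0.4)", "12.3")
# into value (NA when unknown) and below-threshold flag
parse_frac_tokens <- function(x) {
  bt <- grepl("^BT", x)
  val <- suppressWarnings(as.numeric(x))
  par <- regmatches(x, regexpr("\\(([0-9.]+)\\)", x))
  has_par <- bt & lengths(regmatches(x, gregexpr("\\(", x))) > 0
  val[has_par] <- as.numeric(gsub("[()]", "", par))
  list(value = val, below = bt)
}

#' Microarray ligand lists (bundled table 1)
#'
#' Ligands called expressed (anchor Ntf3) in uninjured, 3 DPI and 7 DPI
#' whole-nerve microarrays, plus the printed triple intersection. Markers
#' record condition-privacy annotations from the source (`*` uninjured only,
#' `**` 3 DPI only, `+` 7 DPI only, `++` both injured conditions only).
#'
#' @return list of `gene_set`s (`uninjured`, `dpi3`, `dpi7`, `intersect`) and
#'   `markers`, a data.frame (condition, gene, marker).
#' @export
nerve_table1 <- function() {
  tab <- read_fixture("table1.tsv")
  sets <- lapply(split(tab$gene, tab$condition), gene_set)
  out <- sets[c("uninjured", "dpi3", "dpi7", "intersect")]
  names(out) <- c("uninjured", "dpi3", "dpi7", "intersect")
  tab$gene <- norm_genes(tab$gene)
  c(out, list(markers = tab))
}

# internal: build a detection_table + marker vector from a fixture with
# gene, marker, then per-cell-type token columns
fixture_detection <- function(file) {
  tab <- read_fixture(file)
  types <- setdiff(names(tab), c("gene", "marker"))
  genes <- norm_genes(tab$gene)
  frac <- matrix(NA_real_, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
  below <- matrix(FALSE, nrow = length(genes), ncol = length(types),
                  dimnames = list(genes, types))
  for (t in types) {
    p <- parse_frac_tokens(tab[[t]])
    frac[, t] <- p$value
    below[, t] <- p$below
  }
  dt <- detection_table(frac, below = below)
  attr(dt, "marker") <- stats::setNames(tab$marker, genes)
  dt
}

#' Injured-nerve ligand detection fractions (bundled table 2)
#'
#' Percentage of cells per injured-nerve cell type detectably expressing each
#' of the 143 injured-nerve ligands. Columns include the two Pdgfra-positive
#' mesenchymal compartments and their pooled `combined_mesenchymal` aggregate
#' (exclude the aggregate from highest-type comparisons). The `marker`
#' attribute carries the source's per-ligand annotation: `*` expressed in
#' >= 2% of mesenchymal cells, `**` additionally highest in a mesenchymal
#' compartment (computed by the original analysis from unrounded fractions,
#' so it resolves ties at the printed precision).
#'
#' @return `detection_table` with a `marker` attribute.
#' @export
nerve_table2 <- function() fixture_detection("table2.tsv")

#' Uninjured-nerve ligand detection fractions (bundled table 3)
#' @return `detection_table` with a `marker` attribute (see [nerve_table2()]).
#' @export
nerve_table3 <- function() fixture_detection("table3.tsv")

#' Neonatal-nerve ligand detection fractions (bundled table 4)
#' @return `detection_table` with a `marker` attribute (see [nerve_table2()]).
#' @export
nerve_table4 <- function() fixture_detection("table4.tsv")

#' Combined Schwann-cell dataset detection fractions (bundled table 5)
#'
#' Fractions per Schwann-cell state (neonatal, uninjured myelinating,
#' uninjured non-myelinating, injured) with the printed injured:uninjured
#' (non-myelinating) fold-change column. Below-threshold entries carry the
#' parenthetical raw percentage used for the fold changes.
#'
#' @return list: `table` (`detection_table`), `injured_highest` (`gene_set`),
#'   `fold_display` (named character, printed fold-change tokens incl.
#'   lower-bound `">x"` and undefined `"-"` markers).
#' @export
nerve_table5 <- function() {
  tab <- read_fixture("table5.tsv")
  types <- c("neonatal", "uninjured_myelinating", "uninjured_nonmyelinating",
             "injured")
  genes <- norm_genes(tab$gene)
  frac <- matrix(NA_real_, length(genes), length(types),
                 dimnames = list(genes, types))
  below <- matrix(FALSE, length(genes), length(types),
                  dimnames = list(genes, types))
  for (t in types) {
    p <- parse_frac_tokens(tab[[t]])
    frac[, t] <- p$value
    below[, t] <- p$below
  }
  list(table = detection_table(frac, below = below),
       injured_highest = gene_set(genes[tab$injured_highest == "1"],
                                  name = "injured_highest"),
       fold_display = stats::setNames(tab$fold_change, genes))
}

#' Combined mesenchymal-cell dataset detection fractions (bundled table 6)
#'
#' Fractions per mesenchymal cluster with the printed injured:uninjured
#' endoneurial fold-change column.
#'
#' @return list: `table` (`detection_table`), `fold_display` (named
#'   character).
#' @export
nerve_table6 <- function() {
  tab <- read_fixture("table6.tsv")
  types <- setdiff(names(tab), c("gene", "fold_change"))
  genes <- norm_genes(tab$gene)
  frac <- matrix(NA_real_, length(genes), length(types),
                 dimnames = list(genes, types))
  below <- matrix(FALSE, length(genes), length(types),
                  dimnames = list(genes, types))
  for (t in types) {
    p <- parse_frac_tokens(tab[[t]])
    frac[, t] <- p$value
    below[, t] <- p$below
  }
  list(table = detection_table(frac, below = below),
       fold_display = stats::setNames(tab$fold_change, genes))
}

#' Neuronal cell-surface proteomes (bundled table 7)
#'
#' Proteins detected by cell-surface capture mass spectrometry on cultured
#' sensory (DRG) and sympathetic (SCG) neurons, and the printed intersection.
#'
#' @return list of `gene_set`s: `drg`, `scg`, `shared`.
#' @export
nerve_table7 <- function() {
  tab <- read_fixture("table7.tsv")
  sets <- lapply(split(tab$gene, tab$list), gene_set)
  sets[c("drg", "scg", "shared")]
}

#' Sensory and sympathetic neuron receptors (bundled table 8)
#'
#' Mass-spectrometry receptor lists (DRG-only, SCG-only, shared) and the
#' microarray receptor repertoires called with the proteomics-anchored
#' cutoffs (DRGs: Itgam anchor; SCGs: Sorcs3 anchor).
#'
#' @return list with `ms` (`drg_only`, `scg_only`, `shared`) and `array`
#'   (`drg`, `scg`), all `gene_set`s.
#' @export
nerve_table8 <- function() {
  tab <- read_fixture("table8.tsv")
  s <- lapply(split(tab$gene, tab$list), gene_set)
  list(ms = list(drg_only = s$ms_drg_only, scg_only = s$ms_scg_only,
                 shared = s$ms_shared),
       array = list(drg = s$array_drg, scg = s$array_scg))
}

#' Printed interaction models (bundled table 9)
#'
#' All predicted unidirectional injured-nerve ligand to neuron receptor
#' interactions for the four target populations (SCGs, DRGs, MNs, RGCs), as
#' an edge table.
#'
#' @param population optional filter: one of `"SCGs"`, `"DRGs"`, `"MNs"`,
#'   `"RGCs"`.
#' @return data.frame with columns `population`, `source`, `ligand`,
#'   `target`, `receptor` (symbols case-normalized).
#' @export
nerve_table9 <- function(population = NULL) {
  tab <- read_fixture("table9.tsv")
  out <- data.frame(population = tab$population,
                    source = tolower(tab$source_cell),
                    ligand = norm_genes(tab$ligand),
                    target = tab$target_cell,
                    receptor = norm_genes(tab$receptor))
  if (!is.null(population)) {
    population <- match.arg(population, c("SCGs", "DRGs", "MNs", "RGCs"))
    out <- out[out$population == population, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Motor neuron and RGC receptor repertoires (bundled table 10)
#'
#' Receptors called on motor neurons (microarray, top-87%-of-mRNAs cutoff)
#' and on retinal ganglion cells (RNA-seq, FPKM > 1), with the printed
#' cross-population intersect columns.
#'
#' @return list of `gene_set`s: `mn`, `drg_scg_mn`, `rgc`, `all_four`.
#' @export
nerve_table10 <- function() {
  tab <- read_fixture("table10.tsv")
  s <- lapply(split(tab$gene, tab$list), gene_set)
  s[c("mn", "drg_scg_mn", "rgc", "all_four")]
}
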