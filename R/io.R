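#' Read a digital gene expression (DGE) matrix
#'
#' Reads a genes x cells UMI count matrix either as a MatrixMarket coordinate
#' triplet (with companion `genes.tsv` / `barcodes.tsv` files, 1-based
#' indices) or as a dense TSV with genes as rows and cells as columns. Gene
#' symbols are canonicalized to uppercase for matching; the original spelling
#' is kept as a display name.
#'
#' @param path path to the matrix file (`.mtx` for triplet format) or dense
#'   TSV.
#' @param format `"mtx-triplet"` or `"dense-tsv"`. Guessed from the file
#'   extension when missing.
#' @param genes,barcodes companion file paths for the triplet format; default
#'   to `genes.tsv` / `barcodes.tsv` next to the matrix file.
#' @return object of class `dge_matrix`: a list with `counts` (sparse
#'   `dgCMatrix`, rownames = canonical gene symbols, colnames = barcodes) and
#'   `gene_display` (named character, original symbol spelling).
#' @export
read_dge <- function(path, format = c("mtx-triplet", "dense-tsv"),
                     genes = NULL, barcodes = NULL) {
  if (missing(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx-triplet" else "dense-tsv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx-triplet") {
    counts <- Matrix::readMM(path)
    # readMM may return pattern/symmetric storage; force general numeric
    counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    gid <- readLines(genes)
    bid <- readLines(barcodes)
    gid <- vapply(strsplit(gid, "\t"), `[`, "", 1L)
    bid <- vapply(strsplit(bid, "\t"), `[`, "", 1L)
    if (length(gid) != nrow(counts) || length(bid) != ncol(counts)) {
      stop("companion gene/barcode lists do not match matrix dimensions",
           call. = FALSE)
    }
    dimnames(counts) <- list(gid, bid)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, row.names = NULL)
    if (nrow(tab) == 0L || ncol(tab) < 2L) stop("no cells", call. = FALSE)
    gid <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    counts <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    dimnames(counts) <- list(gid, colnames(tab)[-1L])
  }
  new_dge(counts)
}

# internal constructor + invariant checks for dge_matrix
new_dge <- function(counts) {
  if (ncol(counts) == 0L) stop("no cells", call. = FALSE)
  if (nrow(counts) == 0L) stop("no genes", call. = FALSE)
  x <- counts@x
  if (any(x < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(x != round(x))) stop("non-integer counts are not allowed", call. = FALSE)
  display <- rownames(counts)
  canon <- norm_genes(display)
  check_unique(canon, "gene")
  check_unique(colnames(counts), "cell")
  rownames(counts) <- canon
  structure(list(counts = counts,
                 gene_display = stats::setNames(display, canon)),
            class = "dge_matrix")
}

#' @export
print.dge_matrix <- function(x, ...) {
  cat(sprintf("<dge_matrix: %d genes x %d cells, %d nonzero counts>\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' Write a DGE matrix as MatrixMarket triplet plus companion lists
#'
#' @param dge a `dge_matrix`.
#' @param dir output directory; written files are `matrix.mtx`, `genes.tsv`
#'   and `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_dge <- function(dge, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dge$counts, file.path(dir, "matrix.mtx"))
  writeLines(unname(dge$gene_display[rownames(dge$counts)]),
             file.path(dir, "genes.tsv"))
  writeLines(colnames(dge$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read per-cell annotations
#'
#' Annotation TSV with columns `cell_id`, `cell_type`, optional `dataset` and
#' `group`.
#'
#' @param path TSV path.
#' @return data.frame with one row per cell.
#' @export
read_cell_annotations <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  need <- c("cell_id", "cell_type")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("missing annotation column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  check_unique(ann$cell_id, "cell")
  if (any(!nzchar(ann$cell_type))) stop("empty cell_type label", call. = FALSE)
  ann
}

#' Read a bulk expression profile set
#'
#' Dense TSV, genes as rows, one column per condition. Values are normalized
#' expression (log2 intensity or FPKM; record the unit via `units`).
#'
#' @param path TSV path with a gene column followed by condition columns.
#' @param units declared unit of the values (free text, e.g. `"log2"` or
#'   `"fpkm"`).
#' @return object of class `bulk_profile`: numeric matrix (genes x
#'   conditions, rownames canonical) with a `units` attribute.
#' @export
read_bulk_profiles <- function(path, units = "log2") {
  tab <- utils::read.delim(path, check.names = FALSE)
  gid <- norm_genes(tab[[1L]])
  check_unique(gid, "gene")
  check_unique(colnames(tab)[-1L], "condition")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  if (any(m < 0)) stop("negative expression values", call. = FALSE)
  rownames(m) <- gid
  bulk_profile(m, units = units)
}

#' Construct a bulk profile set from a matrix
#' @param values non-negative numeric matrix, genes x conditions, rownames
#'   gene symbols.
#' @param units declared unit of the values.
#' @return `bulk_profile` object.
#' @export
bulk_profile <- function(values, units = "log2") {
  stopifnot(is.matrix(values), is.numeric(values))
  rownames(values) <- norm_genes(rownames(values))
  check_unique(rownames(values), "gene")
  check_unique(colnames(values), "condition")
  structure(values, units = units, class = c("bulk_profile", class(values)))
}

#' Read a ligand-receptor pair table
#'
#' TSV with (at least) `ligand` and `receptor` columns, case-insensitive
#' header match. Pairs are case-normalized and de-duplicated.
#'
#' @param path TSV path.
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  nm <- tolower(names(tab))
  li <- match("ligand", nm)
  ri <- match("receptor", nm)
  if (is.na(li) || is.na(ri)) {
    stop("pair table must have 'ligand' and 'receptor' columns", call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    return(data.frame(ligand = character(), receptor = character()))
  }
  pairs <- data.frame(ligand = norm_genes(tab[[li]]),
                      receptor = norm_genes(tab[[ri]]))
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
}

#' Read a one-column gene list (optionally with a header)
#' @param path text file, one symbol per line; lines starting with `#` are
#'   skipped.
#' @param name gene-set label.
#' @return `gene_set`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")]
  gene_set(x, name = name)
}

#' Write an interaction network to disk
#'
#' Supported formats: `sif` (Cytoscape simple interaction format, one line per
#' edge `ligand lr receptor`), `graphml` (via igraph; node `kind` attribute
#' distinguishes ligands and receptors) and `tsv` (full edge table). A
#' round-trip through [read_network()] recovers the identical edge set.
#'
#' @param network an `interaction_network`.
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "interaction_network"))
  ed <- network$edges
  ed <- ed[order(ed$ligand, ed$receptor), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(ed)) paste(ed$ligand, "lr", ed$receptor) else character()
    writeLines(lines, path)
  } else {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# internal: igraph representation with node kinds and edge attributes
network_to_igraph <- function(network) {
  ed <- network$edges
  if (nrow(ed) == 0L) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  verts <- data.frame(
    name = c(unique(ed$ligand), unique(ed$receptor)),
    kind = c(rep("ligand", length(unique(ed$ligand))),
             rep("receptor", length(unique(ed$receptor)))))
  # a symbol acting as both ligand and receptor keeps one node per role
  verts$name <- paste(verts$kind, verts$name, sep = ":")
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("ligand:", ed$ligand),
               to = paste0("receptor:", ed$receptor),
               source_cell = ed$source, target = ed$target,
               evidence = ed$evidence),
    directed = TRUE, vertices = verts)
  g
}

#' Read an interaction network written by [write_network()]
#'
#' @param path file path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`; guessed from the extension
#'   when missing.
#' @param target target population label for formats that do not store it
#'   (`sif`).
#' @return `interaction_network`.
#' @export
read_network <- function(path, format = c("tsv", "sif", "graphml"),
                         target = NA_character_) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", "tsv")
  }
  format <- match.arg(format)
  if (format == "tsv") {
    ed <- utils::read.delim(path, colClasses = "character")
    if (nrow(ed) == 0L) return(interaction_network(empty_edges()))
    return(interaction_network(ed))
  }
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(interaction_network(empty_edges()))
    parts <- strsplit(lines, "[ \t]+")
    ed <- data.frame(source = "injured nerve",
                     ligand = vapply(parts, `[`, "", 1L),
                     receptor = vapply(parts, `[`, "", 3L),
                     target = target, evidence = "transcript")
    return(interaction_network(ed))
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0L) return(interaction_network(empty_edges()))
  ends <- igraph::as_data_frame(g, what = "edges")
  ed <- data.frame(source = ends$source_cell,
                   ligand = sub("^ligand:", "", ends$from),
                   receptor = sub("^receptor:", "", ends$to),
                   target = ends$target, evidence = ends$evidence)
  interaction_network(ed)
}
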