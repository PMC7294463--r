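#' Construct a ligand-receptor database
#'
#' A directed set of (ligand, receptor) pairs driving interaction prediction.
#' Receptor-complex membership is annotation only: each receptor of a complex
#' is its own pair, and an interaction is predicted when any cognate receptor
#' is expressed (OR semantics).
#'
#' @param pairs data.frame with `ligand` and `receptor` columns; extra
#'   columns are kept as provenance.
#' @param complex_groups optional named character vector mapping receptor
#'   symbols to complex labels; every label must cover at least two
#'   receptors.
#' @return object of class `lr_db`.
#' @export
lr_db <- function(pairs, complex_groups = NULL) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    stop("pairs need 'ligand' and 'receptor' columns", call. = FALSE)
  }
  pairs$ligand <- norm_genes(pairs$ligand)
  pairs$receptor <- norm_genes(pairs$receptor)
  if (any(!nzchar(pairs$ligand) | !nzchar(pairs$receptor))) {
    stop("empty gene symbol in pair table", call. = FALSE)
  }
  self <- pairs$ligand == pairs$receptor
  if (any(self)) {
    stop("self-pair(s) not allowed: ",
         paste(utils::head(unique(pairs$ligand[self]), 5), collapse = ", "),
         call. = FALSE)
  }
  pairs <- unique(pairs[, c("ligand", "receptor")])
  pairs <- pairs[order(pairs$ligand, pairs$receptor), , drop = FALSE]
  rownames(pairs) <- NULL
  if (!is.null(complex_groups)) {
    names(complex_groups) <- norm_genes(names(complex_groups))
    sizes <- table(complex_groups)
    if (any(sizes < 2L)) {
      stop("complex label(s) covering fewer than 2 receptors: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(pairs = pairs, complex_groups = complex_groups),
            class = "lr_db")
}

#' @export
print.lr_db <- function(x, ...) {
  cat(sprintf("<lr_db: %d pairs, %d ligands, %d receptors>\n",
              nrow(x$pairs), length(unique(x$pairs$ligand)),
              length(unique(x$pairs$receptor))))
  invisible(x)
}

#' Load a ligand-receptor database from a pair TSV
#' @param path TSV with `ligand` and `receptor` columns.
#' @return validated `lr_db`.
#' @export
load_db <- function(path) {
  lr_db(read_pair_table(path))
}

#' Bundled default ligand-receptor database
#'
#' Reconstructed as the union of all ligand-receptor pairs in the bundled
#' interaction-model table (the four target-population blocks of the
#' injured-nerve interaction models). 332 directed pairs over 128 ligands.
#'
#' @return `lr_db`.
#' @export
default_lr_db <- function() {
  edges <- nerve_table9()
  lr_db(data.frame(ligand = edges$ligand, receptor = edges$receptor))
}

#' Receptors cognate to a ligand
#' @param db an `lr_db`.
#' @param ligand ligand symbol (any case). Unknown ligands yield an empty
#'   set.
#' @return sorted character vector of receptor symbols.
#' @export
receptors_of <- function(db, ligand) {
  stopifnot(inherits(db, "lr_db"))
  ligand <- norm_genes(ligand)
  sort(unique(db$pairs$receptor[db$pairs$ligand == ligand]))
}

#' Subset a ligand-receptor database
#'
#' Keeps exactly the pairs whose ligand and receptor both fall in the given
#' sets. Idempotent under repeated subsetting with the same sets.
#'
#' @param db an `lr_db`.
#' @param ligands,receptors character vectors (case-normalized internally).
#' @return `lr_db` with `pairs` a subset of `db$pairs`.
#' @export
subset_db <- function(db, ligands, receptors) {
  stopifnot(inherits(db, "lr_db"))
  ligands <- norm_genes(ligands)
  receptors <- norm_genes(receptors)
  keep <- db$pairs$ligand %in% ligands & db$pairs$receptor %in% receptors
  out <- db
  out$pairs <- db$pairs[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  out
}
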