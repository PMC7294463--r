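# internal: canonical empty edge table
empty_edges <- function() {
  data.frame(source = character(), ligand = character(),
             receptor = character(), target = character(),
             evidence = character())
}

#' Construct an interaction network
#'
#' Directed unidirectional edges from source-tissue ligands to receptors on a
#' target population. Ligand nodes are derived (a ligand with >= 1 cognate
#' expressed receptor); per-ligand annotations (highest source cell type,
#' enrichment flag) and per-receptor evidence labels are attached by
#' [annotate_ligand_sources()] and [mark_protein_evidence()].
#'
#' @param edges data.frame with columns `source`, `ligand`, `receptor`,
#'   `target` and optionally `evidence` (default `"transcript"`).
#' @param ligand_annotations optional data.frame from
#'   [annotate_ligand_sources()].
#' @return object of class `interaction_network`.
#' @export
interaction_network <- function(edges, ligand_annotations = NULL) {
  need <- c("source", "ligand", "receptor", "target")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop("edge table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"evidence" %in% names(edges)) edges$evidence <- "transcript"
  edges$ligand <- norm_genes(edges$ligand)
  edges$receptor <- norm_genes(edges$receptor)
  edges <- unique(edges[, c(need, "evidence")])
  edges <- edges[order(edges$ligand, edges$receptor), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, ligand_annotations = ligand_annotations),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d edges, %d ligand nodes, target %s>\n",
              nrow(x$edges), length(ligand_nodes(x)),
              paste(unique(x$edges$target), collapse = "/")))
  invisible(x)
}

#' Ligand nodes of a network
#'
#' The headline size of an interaction model is its number of ligand nodes: a
#' ligand with at least one cognate expressed receptor counts once however
#' many receptors it reaches.
#'
#' @param network `interaction_network`.
#' @return sorted character vector of ligand symbols.
#' @export
ligand_nodes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  sort(unique(network$edges$ligand))
}

#' Predict unidirectional ligand-receptor interactions
#'
#' The interaction model: an edge (source, ligand, receptor, target) is
#' predicted for every database pair whose ligand is in the source-tissue
#' ligand set and whose receptor is in the target population's receptor
#' call. Receptor complexes use OR semantics (any expressed cognate receptor
#' yields an edge). Output ordering is deterministic (ligand, then receptor,
#' lexicographic).
#'
#' @param ligands source-tissue ligand symbols (e.g. the injured-nerve ligand
#'   panel).
#' @param receptor_call a `receptor_call`, or a character vector of receptor
#'   symbols (then `target` must be given).
#' @param db an `lr_db`.
#' @param source source label for the edges.
#' @param target target population label; defaults to
#'   `receptor_call$population`.
#' @return `interaction_network`.
#' @export
predict_interactions <- function(ligands, receptor_call, db,
                                 source = "injured nerve", target = NULL) {
  stopifnot(inherits(db, "lr_db"))
  if (inherits(receptor_call, "receptor_call")) {
    if (is.null(target)) target <- receptor_call$population
    receptors <- receptor_call$receptors
  } else {
    if (is.null(target)) stop("target population label required", call. = FALSE)
    receptors <- receptor_call
  }
  ligands <- norm_genes(ligands)
  receptors <- norm_genes(receptors)
  if (nrow(db$pairs) == 0L) {
    warning("empty ligand-receptor database: empty network", call. = FALSE)
    return(interaction_network(empty_edges()))
  }
  keep <- db$pairs$ligand %in% ligands & db$pairs$receptor %in% receptors
  hits <- db$pairs[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(interaction_network(empty_edges()))
  interaction_network(data.frame(source = source, ligand = hits$ligand,
                                 receptor = hits$receptor, target = target,
                                 evidence = "transcript"))
}

#' Annotate network ligands with their source cell type
#'
#' For each ligand node, records the source-tissue cell type with the highest
#' detection fraction (strict maximum; ties surfaced) and whether the ligand
#' is expressed at `factor`-fold higher levels in that type than in every
#' other compared type.
#'
#' @param network `interaction_network`.
#' @param detection `detection_table` over the source tissue; every network
#'   ligand must be present.
#' @param compare_types,mesenchymal_members,tie_break passed to
#'   [assign_highest()].
#' @param factor enrichment fold for the flag; default 4.
#' @return the network with a `ligand_annotations` data.frame (columns
#'   `gene`, `assigned`, `top_types`, `tie`, `max_fraction`, `enriched`).
#' @export
annotate_ligand_sources <- function(network, detection, compare_types = NULL,
                                    mesenchymal_members = NULL,
                                    factor = 4, tie_break = NULL) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(detection, "detection_table"))
  lig <- ligand_nodes(network)
  missing <- setdiff(lig, rownames(detection$fraction))
  if (length(missing)) {
    stop("network ligand(s) absent from detection table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ah <- assign_highest(detection, compare_types = compare_types,
                       mesenchymal_members = mesenchymal_members,
                       tie_break = tie_break)
  ah <- ah[ah$gene %in% lig, , drop = FALSE]
  if (is.null(compare_types)) compare_types <- colnames(detection$fraction)
  flagged <- character(0)
  for (t in compare_types) {
    enr <- enrichment_flags(detection, t, factor = factor,
                            compare_types = setdiff(compare_types, t))
    flagged <- c(flagged, intersect(enr, ah$gene[!is.na(ah$assigned) &
                                                   ah$assigned == t]))
  }
  ah$enriched <- ah$gene %in% flagged
  rownames(ah) <- NULL
  network$ligand_annotations <- ah
  network
}

#' Label edges with protein-level receptor evidence
#'
#' @param network `interaction_network`.
#' @param proteome_receptors receptor symbols detected at the protein level
#'   (may be empty).
#' @return network with `evidence` set to `"transcript+protein"` on edges
#'   whose receptor is in the proteome set, `"transcript"` otherwise.
#' @export
mark_protein_evidence <- function(network, proteome_receptors) {
  stopifnot(inherits(network, "interaction_network"))
  prot <- norm_genes(proteome_receptors)
  network$edges$evidence <-
    ifelse(network$edges$receptor %in% prot, "transcript+protein",
           "transcript")
  network
}

#' Compare interaction networks across target populations
#'
#' Region counts over 2-4 networks at the ligand-node level or the
#' (ligand, receptor) pair level, with per-network unique lists and the full
#' shared core.
#'
#' @param networks named list of 2-4 `interaction_network`s.
#' @param level `"ligand"` or `"pair"`.
#' @return list with `counts` (named integer vector over all non-empty region
#'   patterns, names joined with `&`), `regions` (member lists), `shared`
#'   (items common to all networks) and `unique` (per-network private items).
#' @export
compare_networks <- function(networks, level = c("ligand", "pair")) {
  level <- match.arg(level)
  if (!is.list(networks) || length(networks) < 2L || length(networks) > 4L) {
    stop("compare_networks supports 2 to 4 networks", call. = FALSE)
  }
  if (is.null(names(networks))) names(networks) <- LETTERS[seq_along(networks)]
  items <- lapply(networks, function(nw) {
    stopifnot(inherits(nw, "interaction_network"))
    if (level == "ligand") ligand_nodes(nw)
    else unique(paste(nw$edges$ligand, nw$edges$receptor, sep = "->"))
  })
  universe <- sort(unique(unlist(items)))
  membership <- vapply(items, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- region_patterns(names(networks))
  regions <- lapply(patterns, function(p) {
    inside <- rep(TRUE, length(universe))
    for (nm in names(networks)) {
      inside <- inside & (membership[, nm] == (nm %in% p))
    }
    universe[inside]
  })
  names(regions) <- vapply(patterns, paste, "", collapse = "&")
  uniq <- regions[names(networks)]
  list(counts = vapply(regions, length, integer(1L)),
       regions = regions,
       shared = Reduce(intersect, items),
       unique = uniq)
}
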