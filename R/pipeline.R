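#' Run the end-to-end ligand-receptor pipeline
#'
#' Orchestrates a full run from a single configuration list: obtain a count
#' matrix (simulated from a `sim_config` or loaded from disk), compute
#' per-cell-type detection fractions and expressed sets, call target
#' receptors (a receptor list may be supplied directly), predict the
#' interaction network against a ligand-receptor database, and write every
#' stage output plus a manifest. Re-running with an identical configuration
#' reproduces identical files.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{simulate}{a `sim_config`, or NULL when loading from disk}
#'     \item{dge, annot}{paths to a matrix (MTX dir or dense TSV) and an
#'       annotation TSV, used when `simulate` is NULL}
#'     \item{genes}{optional ligand panel restricting the abundance stage}
#'     \item{detection_threshold}{percent, default 2}
#'     \item{receptors}{character vector: the target population's receptor
#'       repertoire (optional; skips the network stage when absent)}
#'     \item{target}{target population label, default `"target"`}
#'     \item{db}{an `lr_db`; default [default_lr_db()]}
#'   }
#' @param out_dir output directory (created).
#' @return invisible list with the in-memory stage results (`detection`,
#'   `expressed`, `network`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  thr <- config$detection_threshold %||% 2
  if (!(thr > 0 && thr <= 100)) {
    stop("stage 'config': detection_threshold must lie in (0, 100]",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_dge(config$simulate))
    dge <- sim$dge
    annot <- sim$annot
    stage("simulate", {
      write_dge(dge, file.path(out_dir, "dge"))
      utils::write.table(annot, file.path(out_dir, "annotations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(gene = rownames(sim$truth$fraction),
                   round(sim$truth$fraction, 6), check.names = FALSE),
        file.path(out_dir, "truth_detection.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    })
  } else {
    dge <- stage("load", read_dge(config$dge))
    annot <- stage("load", read_cell_annotations(config$annot))
  }

  detection <- stage("abundance",
                     detection_fractions(dge, annot, genes = config$genes))
  utils::write.table(
    data.frame(gene = rownames(detection$fraction),
               round(detection$fraction, 6), check.names = FALSE),
    file.path(out_dir, "detection_fractions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  expressed <- stage("expressed_sets", expressed_sets(detection, thr))
  exp_tab <- data.frame(
    cell_type = rep(names(expressed), lengths(expressed)),
    gene = unlist(expressed, use.names = FALSE))
  utils::write.table(exp_tab, file.path(out_dir, "expressed_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  network <- NULL
  if (!is.null(config$receptors)) {
    db <- config$db %||% default_lr_db()
    network <- stage("network",
                     predict_interactions(expressed$any_type,
                                          config$receptors, db,
                                          target = config$target %||% "target"))
    network <- stage("network",
                     annotate_ligand_sources(network, detection))
    write_network(network, file.path(out_dir, "network.tsv"), "tsv")
    write_network(network, file.path(out_dir, "network.sif"), "sif")
  }

  manifest <- list(
    package = "nerveLR",
    version = as.character(utils::packageVersion("nerveLR")),
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    detection_threshold = thr,
    n_genes = nrow(dge$counts), n_cells = ncol(dge$counts),
    n_cell_types = length(unique(annot$cell_type)),
    n_edges = if (is.null(network)) 0L else nrow(network$edges),
    n_ligand_nodes = if (is.null(network)) 0L else length(ligand_nodes(network)),
    outputs = sort(list.files(out_dir, recursive = TRUE)))
  manifest$checksums <- vapply(
    setdiff(manifest$outputs, "manifest.json"), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }, "")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(detection = detection, expressed = expressed,
                 network = network, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
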