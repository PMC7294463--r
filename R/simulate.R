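#' Configuration for the synthetic single-cell count generator
#'
#' Defines the study conditions of a simulated droplet scRNA-seq experiment:
#' cell types with their sizes, per-gene per-type detection probabilities,
#' and the count model for expressed cells (zero-truncated negative
#' binomial). Optional batches act purely as sequencing-depth multipliers.
#'
#' @param cell_types named integer vector: cells per cell type (all >= 1).
#' @param genes gene symbols.
#' @param detect_prob detection probabilities in \[0, 1\]: a single number, a
#'   per-gene vector, or a genes x cell-types matrix.
#' @param mean_expr positive mean count given detection (scalar or per-gene).
#' @param dispersion negative-binomial overdispersion >= 0 (0 = Poisson);
#'   variance is `mu + dispersion * mu^2`.
#' @param batches optional data.frame with columns `name`, `fraction`
#'   (summing to 1) and `depth` (library-depth multiplier).
#' @param seed integer seed; mandatory, no global random state is consulted.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(cell_types, genes, detect_prob, mean_expr = 2,
                       dispersion = 0.5, batches = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (is.null(names(cell_types)) || any(cell_types < 1)) {
    stop("cell_types must be a named vector of counts >= 1", call. = FALSE)
  }
  genes <- norm_genes(genes)
  check_unique(genes, "gene")
  nt <- length(cell_types)
  ng <- length(genes)
  p <- detect_prob
  if (!is.matrix(p)) p <- matrix(p, nrow = ng, ncol = nt)
  dimnames(p) <- list(genes, names(cell_types))
  if (any(p < 0 | p > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  mu <- rep_len(mean_expr, ng)
  if (any(mu <= 0)) stop("mean_expr must be positive", call. = FALSE)
  disp <- rep_len(dispersion, ng)
  if (any(disp < 0)) stop("dispersion must be >= 0", call. = FALSE)
  if (!is.null(batches)) {
    stopifnot(all(c("name", "fraction", "depth") %in% names(batches)))
    if (abs(sum(batches$fraction) - 1) > 1e-8) {
      stop("batch fractions must sum to 1", call. = FALSE)
    }
  }
  structure(list(cell_types = cell_types, genes = genes, detect_prob = p,
                 mean_expr = stats::setNames(mu, genes),
                 dispersion = stats::setNames(disp, genes),
                 batches = batches, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: zero-truncated counts given detection; depth scales the mean
rcount_truncated <- function(n, mu, disp) {
  if (n == 0L) return(integer(0))
  if (disp == 0) {
    p0 <- stats::dpois(0, mu)
    u <- stats::runif(n, p0, 1)
    stats::qpois(u, mu)
  } else {
    size <- 1 / disp
    p0 <- stats::dnbinom(0, size = size, mu = mu)
    u <- stats::runif(n, p0, 1)
    stats::qnbinom(u, size = size, mu = mu)
  }
}

#' Simulate a sparse digital gene expression matrix
#'
#' Each cell of type `t` expresses gene `g` independently with probability
#' `detect_prob[g, t]`; expressed cells draw a count >= 1 from a
#' zero-truncated negative binomial whose mean is scaled by the cell's batch
#' depth multiplier. The realized detection probability is unaffected by
#' batch depth, so the truth table is exactly `detect_prob * 100`.
#'
#' @param config a `sim_config`.
#' @return list with `dge` (a `dge_matrix`), `annot` (cell annotations:
#'   `cell_id`, `cell_type`, `dataset` = batch name) and `truth`
#'   (`detection_table` of generating percentages).
#' @export
simulate_dge <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  types <- names(config$cell_types)
  genes <- config$genes
  cells <- character(0)
  cell_type <- character(0)
  depth <- numeric(0)
  batch_of <- character(0)
  for (t in types) {
    n <- config$cell_types[[t]]
    ids <- sprintf("%s_c%04d", t, seq_len(n))
    cells <- c(cells, ids)
    cell_type <- c(cell_type, rep(t, n))
    if (is.null(config$batches)) {
      depth <- c(depth, rep(1, n))
      batch_of <- c(batch_of, rep("batch1", n))
    } else {
      # deterministic proportional split, remainder to the largest batch
      nb <- diff(round(cumsum(c(0, config$batches$fraction)) * n))
      bid <- rep(config$batches$name, nb)
      depth <- c(depth, rep(config$batches$depth, nb))
      batch_of <- c(batch_of, bid)
    }
  }
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (ti in seq_along(types)) {
    jcells <- which(cell_type == types[ti])
    for (gi in seq_along(genes)) {
      p <- config$detect_prob[gi, ti]
      if (p == 0) next
      on <- jcells[stats::runif(length(jcells)) < p]
      if (!length(on)) next
      mu <- config$mean_expr[gi] * depth[on]
      cnt <- vapply(mu, function(m) {
        rcount_truncated(1L, m, config$dispersion[gi])
      }, numeric(1))
      ii <- c(ii, rep.int(gi, length(on)))
      jj <- c(jj, on)
      xx <- c(xx, cnt)
    }
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(genes), length(cells)),
                                 dimnames = list(genes, cells))
  annot <- data.frame(cell_id = cells, cell_type = cell_type,
                      dataset = batch_of)
  truth <- detection_table(config$detect_prob * 100,
                           n_cells = config$cell_types)
  list(dge = new_dge(counts), annot = annot, truth = truth)
}

#' Simulate a rank-structured bulk profile containing an anchor gene
#'
#' Draws log-normal expression for a gene universe of size `n_genes_total`
#' (the given symbols padded with synthetic filler genes) and places the
#' anchor gene so that the fraction of genes expressed at or below it equals
#' `anchor_quantile` exactly (to 1/n): the anchor value is set midway between
#' the bracketing order statistics of the other genes.
#'
#' @param genes gene symbols that must appear in the profile (anchor
#'   included).
#' @param n_genes_total total universe size (>= length(genes)).
#' @param anchor anchor gene symbol, must be in `genes`.
#' @param anchor_quantile target at-or-below fraction, in (0, 1\].
#' @param seed integer seed.
#' @param condition condition name of the single output column.
#' @param meanlog,sdlog log-normal parameters of the background.
#' @return single-condition `bulk_profile`.
#' @export
simulate_bulk <- function(genes, n_genes_total, anchor, anchor_quantile,
                          seed, condition = "sim", meanlog = 4, sdlog = 1.5) {
  genes <- unique(norm_genes(genes))
  anchor <- norm_genes(anchor)
  if (!anchor %in% genes) stop("anchor gene missing from gene list",
                               call. = FALSE)
  if (!(anchor_quantile > 0 && anchor_quantile <= 1)) {
    stop("anchor_quantile must lie in (0, 1]", call. = FALSE)
  }
  if (n_genes_total < length(genes)) {
    stop("n_genes_total smaller than the gene list", call. = FALSE)
  }
  set.seed(seed)
  n_fill <- n_genes_total - length(genes)
  fill <- if (n_fill > 0) sprintf("FILLER%06d", seq_len(n_fill)) else character()
  ids <- c(genes, fill)
  vals <- stats::rlnorm(n_genes_total, meanlog = meanlog, sdlog = sdlog)
  names(vals) <- ids
  others <- sort(vals[names(vals) != anchor])
  k <- max(1L, round(anchor_quantile * n_genes_total))
  vals[anchor] <- if (k > length(others)) {
    others[length(others)] * 1.01
  } else if (k == 1L) {
    others[1L] / 2
  } else {
    (others[k - 1L] + others[k]) / 2
  }
  bulk_profile(matrix(vals, ncol = 1, dimnames = list(ids, condition)),
               units = "sim")
}

#' Simulate a partially sensitive surface-proteome detection list
#'
#' Each true receptor is detected independently with probability
#' `sensitivity`; each decoy (non-receptor) gene with probability
#' `fdr_like`. The two sets must be disjoint.
#'
#' @param true_receptors receptor symbols truly present.
#' @param sensitivity detection probability for true receptors, in \[0, 1\].
#' @param decoys symbols not truly present.
#' @param fdr_like spurious detection probability for decoys, in \[0, 1\].
#' @param seed integer seed.
#' @return `gene_set` of detected symbols.
#' @export
simulate_proteome <- function(true_receptors, sensitivity,
                              decoys = character(), fdr_like = 0, seed) {
  truth <- unique(norm_genes(true_receptors))
  dec <- unique(norm_genes(decoys))
  if (length(intersect(truth, dec))) {
    stop("true receptors and decoys must be disjoint", call. = FALSE)
  }
  stopifnot(sensitivity >= 0, sensitivity <= 1, fdr_like >= 0, fdr_like <= 1)
  set.seed(seed)
  hit <- truth[stats::runif(length(truth)) < sensitivity]
  fp <- dec[stats::runif(length(dec)) < fdr_like]
  gene_set(c(hit, fp), name = "detected_proteome")
}
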