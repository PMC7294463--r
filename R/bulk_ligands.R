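#' Anchor-gene threshold for a bulk profile
#'
#' The expression cutoff for calling genes expressed in a bulk profile is the
#' expression of a chosen anchor gene (for nerve ligand calling, Ntf3). The
#' anchor's percentile reports where that cutoff sits in the whole profile:
#' by default the percentage of probed genes expressed at or below the anchor
#' (ties counted at-or-below); `"strictly_below"` gives the alternative
#' convention.
#'
#' @param profile a `bulk_profile`.
#' @param condition condition column to use.
#' @param anchor anchor gene symbol.
#' @param percentile_mode `"at_or_below"` (default) or `"strictly_below"`.
#' @return list with `threshold_value` and `anchor_percentile` (0-100).
#' @export
anchor_threshold <- function(profile, condition, anchor,
                             percentile_mode = c("at_or_below",
                                                 "strictly_below")) {
  percentile_mode <- match.arg(percentile_mode)
  anchor <- norm_genes(anchor)
  if (!anchor %in% rownames(profile)) {
    stop("anchor gene absent from profile: ", anchor, call. = FALSE)
  }
  vals <- profile[, condition]
  thr <- vals[[anchor]]
  pct <- if (percentile_mode == "at_or_below") {
    100 * sum(vals <= thr) / length(vals)
  } else {
    100 * sum(vals < thr) / length(vals)
  }
  list(threshold_value = unname(thr), anchor_percentile = pct)
}

#' Call expressed ligands in a bulk profile by anchor thresholding
#'
#' A panel ligand is called expressed when its value is at or above the
#' anchor gene's expression (inclusive comparison: the anchor calls itself
#' expressed). Panel genes missing from the profile are reported, not
#' silently dropped.
#'
#' @param profile a `bulk_profile`.
#' @param condition condition column.
#' @param ligand_panel character vector of candidate ligand symbols
#'   (non-empty).
#' @param anchor anchor gene symbol.
#' @return object of class `expressed_set_result`: list with `condition`,
#'   `threshold_value`, `anchor_percentile`, `expressed` (a `gene_set`
#'   including the anchor) and `missing` (panel genes absent from the
#'   profile).
#' @export
call_expressed_ligands <- function(profile, condition, ligand_panel, anchor) {
  panel <- unique(norm_genes(ligand_panel))
  if (!length(panel)) stop("empty ligand panel", call. = FALSE)
  at <- anchor_threshold(profile, condition, anchor)
  vals <- profile[, condition]
  present <- intersect(panel, rownames(profile))
  missing <- setdiff(panel, present)
  if (length(missing)) {
    warning(sprintf("%d panel gene(s) absent from profile: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
  }
  expressed <- present[vals[present] >= at$threshold_value]
  structure(list(condition = condition,
                 threshold_value = at$threshold_value,
                 anchor_percentile = at$anchor_percentile,
                 expressed = gene_set(c(expressed, norm_genes(anchor)),
                                      name = condition),
                 missing = missing),
            class = "expressed_set_result")
}

#' @export
print.expressed_set_result <- function(x, ...) {
  cat(sprintf(
    "<expressed_set_result '%s': %d ligands, threshold %.4g (%.1f%% of genes at or below)>\n",
    x$condition, length(x$expressed), x$threshold_value, x$anchor_percentile))
  invisible(x)
}

#' Disjoint Venn region counts for two or three gene sets
#'
#' Regions are named by the sets they belong to, joined with `&` (e.g. for
#' sets A, B, C: `"A"`, `"A&B"`, `"A&B&C"`, ...). Every element of the union
#' falls in exactly one region, so the counts sum to the union size.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return list with `counts` (named integer vector over the non-empty
#'   pattern space, zeros included) and `regions` (named list of member
#'   vectors).
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L) {
    stop("venn_counts supports 2 or 3 sets", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, norm_genes)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- region_patterns(names(sets))
  regions <- lapply(patterns, function(p) {
    inside <- rep(TRUE, length(universe))
    for (nm in names(sets)) {
      want <- nm %in% p
      inside <- inside & (membership[, nm] == want)
    }
    universe[inside]
  })
  names(regions) <- vapply(patterns, paste, "", collapse = "&")
  list(counts = vapply(regions, length, integer(1L)), regions = regions)
}

# internal: all non-empty subsets of the set names, smallest first
region_patterns <- function(nms) {
  k <- length(nms)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(nms, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}
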