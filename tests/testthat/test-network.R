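test_that("interaction prediction equals the brute-force cross join", {
  set.seed(17)
  ligs <- sprintf("L%02d", 1:50)
  recs <- sprintf("R%02d", 1:50)
  pairs <- unique(data.frame(ligand = sample(ligs, 120, TRUE),
                             receptor = sample(recs, 120, TRUE)))
  db <- lr_db(pairs)
  have_l <- sample(ligs, 30)
  have_r <- sample(recs, 25)
  nw <- predict_interactions(have_l, have_r, db, target = "pop")
  brute <- character(0)
  for (l in have_l) for (r in have_r) {
    if (any(db$pairs$ligand == l & db$pairs$receptor == r)) {
      brute <- c(brute, paste(l, r))
    }
  }
  expect_setequal(paste(nw$edges$ligand, nw$edges$receptor), brute)
  expect_lte(length(ligand_nodes(nw)), nrow(nw$edges))
})

test_that("edge ordering is deterministic and empty inputs degrade gracefully", {
  db <- toy_db(list(c("B", "R2"), c("A", "R9"), c("A", "R1")))
  nw <- predict_interactions(c("B", "A"), c("R9", "R1", "R2"), db,
                             target = "pop")
  expect_equal(paste(nw$edges$ligand, nw$edges$receptor),
               c("A R1", "A R9", "B R2"))
  expect_equal(nrow(predict_interactions("Z", c("R1"), db,
                                         target = "pop")$edges), 0)
  empty_db <- lr_db(data.frame(ligand = character(),
                               receptor = character()))
  expect_warning(out <- predict_interactions("A", "R1", empty_db,
                                             target = "pop"),
                 "empty")
  expect_equal(nrow(out$edges), 0)
})

test_that("adding a receptor to the call never removes an edge", {
  db <- toy_db(list(c("A", "R1"), c("A", "R2"), c("B", "R2"), c("C", "R3")))
  ligs <- c("A", "B", "C")
  small <- predict_interactions(ligs, c("R1"), db, target = "p")
  large <- predict_interactions(ligs, c("R1", "R2"), db, target = "p")
  expect_true(all(paste(small$edges$ligand, small$edges$receptor) %in%
                    paste(large$edges$ligand, large$edges$receptor)))
})

test_that("the sympathetic-neuron model is reproduced from panel, receptors and database", {
  panel <- expressed_sets(nerve_table2())$any_type
  t8 <- nerve_table8()
  db <- default_lr_db()
  nw <- predict_interactions(panel, t8$array$scg, db, target = "SCGs")
  printed <- nerve_table9("SCGs")
  expect_equal(length(ligand_nodes(nw)), 122)
  expect_setequal(paste(nw$edges$ligand, nw$edges$receptor),
                  paste(printed$ligand, printed$receptor))
})

test_that("sensory-neuron and RGC models are reproduced exactly as well", {
  panel <- expressed_sets(nerve_table2())$any_type
  db <- default_lr_db()
  drg <- predict_interactions(panel, nerve_table8()$array$drg, db,
                              target = "DRGs")
  expect_equal(length(ligand_nodes(drg)), 125)
  expect_setequal(paste(drg$edges$ligand, drg$edges$receptor),
                  paste(nerve_table9("DRGs")$ligand,
                        nerve_table9("DRGs")$receptor))
  rgc <- predict_interactions(panel, nerve_table10()$rgc, db,
                              target = "RGCs")
  expect_equal(length(ligand_nodes(rgc)), 126)
  expect_setequal(paste(rgc$edges$ligand, rgc$edges$receptor),
                  paste(nerve_table9("RGCs")$ligand,
                        nerve_table9("RGCs")$receptor))
})

test_that("network comparisons recover the printed population differences", {
  to_network <- function(pop) {
    ed <- nerve_table9(pop)
    interaction_network(data.frame(source = ed$source, ligand = ed$ligand,
                                   receptor = ed$receptor, target = ed$target))
  }
  nws <- list(SCG = to_network("SCGs"), DRG = to_network("DRGs"),
              MN = to_network("MNs"))
  cmp <- compare_networks(nws[c("SCG", "DRG")], level = "ligand")
  expect_setequal(cmp$unique$DRG, c("GNRH1", "CXCL1", "CXCL2"))
  expect_length(cmp$unique$SCG, 0)
  expect_length(cmp$shared, 122)
  # of the 122 shared sympathetic/sensory ligands, all but EDA reach MNs
  cmp3 <- compare_networks(nws, level = "ligand")
  shared_scg_drg <- intersect(ligand_nodes(nws$SCG), ligand_nodes(nws$DRG))
  expect_length(intersect(shared_scg_drg, ligand_nodes(nws$MN)), 121)
  expect_equal(setdiff(shared_scg_drg, ligand_nodes(nws$MN)), "EDA")
  # identical networks overlap fully
  same <- compare_networks(list(a = nws$SCG, b = nws$SCG), level = "pair")
  expect_length(same$shared, nrow(nws$SCG$edges))
  expect_length(same$unique$a, 0)
  expect_error(compare_networks(list(nws$SCG), level = "ligand"), "2 to 4")
  expect_error(compare_networks(nws, level = "edgecount"))
})

test_that("ligand sources and enrichment flags annotate the network", {
  t2 <- nerve_table2()
  panel <- expressed_sets(t2)$any_type
  nw <- predict_interactions(panel, nerve_table8()$array$scg,
                             default_lr_db(), target = "SCGs")
  nw <- annotate_ligand_sources(nw, t2, compare_types = injured_compare_types)
  ann <- nw$ligand_annotations
  expect_equal(ann$assigned[ann$gene == "BTC"], "schwann")
  expect_true(all(ligand_nodes(nw) %in% ann$gene))
  # sources come from the table's column set
  expect_true(all(stats::na.omit(ann$assigned) %in% injured_compare_types))
  # uniform detection ties; strong focal enrichment flags
  toy <- detection_table(matrix(c(10, 10, 10,
                                  25, 5, 3), nrow = 2, byrow = TRUE,
                                dimnames = list(c("FLAT", "PEAK"),
                                                c("a", "b", "c"))))
  toy_nw <- interaction_network(data.frame(
    source = "nerve", ligand = c("FLAT", "PEAK"),
    receptor = c("R1", "R2"), target = "p"))
  toy_nw <- annotate_ligand_sources(toy_nw, toy)
  expect_true(toy_nw$ligand_annotations$tie[1])
  expect_true(toy_nw$ligand_annotations$enriched[2])  # 25 >= 4 * max(5, 3)
  expect_error(annotate_ligand_sources(toy_nw, detection_table(
    matrix(1, 1, 1, dimnames = list("OTHER", "a")))), "absent")
})

test_that("protein-level evidence marks exactly the proteome-backed receptors", {
  t8 <- nerve_table8()
  nw <- predict_interactions(expressed_sets(nerve_table2())$any_type,
                             t8$array$scg, default_lr_db(), target = "SCGs")
  prot <- unique(c(t8$ms$scg_only, t8$ms$shared))
  nw <- mark_protein_evidence(nw, prot)
  ntrk1 <- nw$edges[nw$edges$receptor == "NTRK1", ]
  expect_true(all(ntrk1$evidence == "transcript+protein"))
  expect_setequal(unique(nw$edges$receptor[nw$edges$evidence ==
                                             "transcript+protein"]),
                  intersect(unique(nw$edges$receptor), prot))
  bare <- mark_protein_evidence(nw, character(0))
  expect_true(all(bare$edges$evidence == "transcript"))
})
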