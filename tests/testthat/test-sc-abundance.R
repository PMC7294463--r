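test_that("detection fractions equal an explicit per-cell loop on small matrices", {
  set.seed(21)
  m <- matrix(rpois(20 * 18, 0.4), nrow = 20)
  dge <- toy_dge(m)
  annot <- toy_annot(colnames(dge$counts),
                     rep(c("schwann", "mesenchymal", "immune"), each = 6))
  dt <- detection_fractions(dge, annot)
  for (t in unique(annot$cell_type)) {
    cells <- annot$cell_id[annot$cell_type == t]
    for (g in rownames(dge$counts)) {
      n_det <- sum(vapply(cells, function(c) dge$counts[g, c] >= 1,
                          logical(1)))
      expect_equal(dt$fraction[g, t], 100 * n_det / length(cells))
    }
  }
  expect_equal(unname(dt$n_cells), rep(6L, 3))
})

test_that("all-zero and all-detected genes hit the 0% and 100% bounds", {
  m <- rbind(zero = rep(0L, 6), one = rep(1L, 6), mixed = c(1, 0, 1, 0, 0, 0))
  dge <- toy_dge(m, genes = rownames(m))
  annot <- toy_annot(colnames(dge$counts), rep(c("a", "b"), each = 3))
  dt <- detection_fractions(dge, annot)
  expect_equal(unname(dt$fraction["ZERO", ]), c(0, 0))
  expect_equal(unname(dt$fraction["ONE", ]), c(100, 100))
})

test_that("fractions are invariant to cell order", {
  set.seed(31)
  m <- matrix(rpois(10 * 12, 0.5), nrow = 10)
  dge <- toy_dge(m)
  annot <- toy_annot(colnames(dge$counts), rep(c("a", "b"), 6))
  perm <- sample(ncol(m))
  dge_p <- toy_dge(m[, perm], cells = colnames(dge$counts)[perm])
  expect_equal(detection_fractions(dge, annot)$fraction,
               detection_fractions(dge_p, annot)$fraction)
})

test_that("simulated detection at p=0.5 recovers within the binomial interval", {
  cfg <- sim_config(c(tA = 5000), "G1", detect_prob = 0.5, seed = 13)
  sim <- simulate_dge(cfg)
  dt <- detection_fractions(sim$dge, sim$annot)
  ci <- 100 * binom99(5000, 0.5)
  expect_gte(dt$fraction["G1", "tA"], ci[1])
  expect_lte(dt$fraction["G1", "tA"], ci[2])
})

test_that("the 2% rule is inclusive and below-threshold entries never qualify", {
  f <- matrix(c(2.0, 1.99, NA, 60.4), ncol = 2,
              dimnames = list(c("BTC", "GDNF"), c("endo", "schwann")))
  dt <- detection_table(f)
  es <- expressed_sets(dt)
  expect_true("BTC" %in% es$endo)       # exactly 2.0 counts as expressed
  expect_false("GDNF" %in% es$endo)     # 1.99 is below threshold
  expect_false("BTC" %in% es$schwann)   # NA = below threshold, value unknown
  expect_true("GDNF" %in% es$schwann)
  es100 <- expressed_sets(dt, threshold = 100)
  expect_length(es100$endo, 0)
  expect_error(expressed_sets(dt, threshold = 150), "\\(0, 100\\]")
})

test_that("highest-type assignment uses the strict maximum and surfaces ties", {
  t2 <- nerve_table2()
  ah <- assign_highest(t2, injured_compare_types)
  pick <- function(g) ah$assigned[ah$gene == g]
  expect_equal(pick("CCL11"), "endoneurial")
  expect_equal(pick("BTC"), "schwann")
  # equal fractions in a two-type toy table tie and stay unassigned
  toy <- detection_table(matrix(c(5, 5), 1, 2,
                                dimnames = list("G1", c("a", "b"))))
  tah <- assign_highest(toy)
  expect_true(tah$tie)
  expect_true(is.na(tah$assigned))
  expect_equal(tah$top_types, "a,b")
  # a tie_break consistent with the leaders resolves it
  tah2 <- assign_highest(toy, tie_break = c(G1 = "b"))
  expect_equal(tah2$assigned, "b")
})

test_that("pooled combined fractions weight members by cell count", {
  f <- matrix(c(10, 50), 1, 2, dimnames = list("G1", c("epi", "endo")))
  dt <- detection_table(f, n_cells = c(epi = 100, endo = 300))
  expect_equal(unname(combined_fraction(dt, c("epi", "endo"))), 40)
  expect_equal(unname(combined_fraction(dt, "epi")), 10)
})

test_that("merging two cell types reproduces the pooled combined fraction", {
  set.seed(41)
  m <- matrix(rpois(8 * 30, 0.6), nrow = 8)
  dge <- toy_dge(m)
  annot <- toy_annot(colnames(dge$counts), rep(c("epi", "endo"), c(10, 20)))
  dt <- detection_fractions(dge, annot)
  merged_annot <- annot
  merged_annot$cell_type <- "mes"
  dt_merged <- detection_fractions(dge, merged_annot)
  expect_equal(combined_fraction(dt, c("epi", "endo")),
               dt_merged$fraction[, "mes"])
})

test_that("fold changes use raw fractions with lower-bound and undefined markers", {
  num <- c(GDNF = 20.5, BMP1 = 46.1, FLAT = 3, NONE = 0, CRLF1 = 30.5)
  den <- c(GDNF = 0, BMP1 = 4.9, FLAT = 3, NONE = 0, CRLF1 = 2.5)
  fc <- fold_changes(num, den)
  row <- function(g) fc[fc$gene == g, ]
  expect_equal(row("GDNF")$display, ">20.5")
  expect_true(is.na(row("GDNF")$ratio))
  expect_equal(row("FLAT")$ratio, 1)
  expect_equal(row("NONE")$display, "-")
  expect_equal(row("CRLF1")$ratio, 12.2)
  expect_equal(row("BMP1")$ratio, 46.1 / 4.9, tolerance = 1e-12)
})

test_that("printed Schwann-cell fold changes agree with recomputation from raw fractions", {
  t5 <- nerve_table5()
  f <- t5$table$fraction
  fc <- fold_changes(f[, "injured"], f[, "uninjured_nonmyelinating"])
  printed <- suppressWarnings(as.numeric(t5$fold_display))
  names(printed) <- names(t5$fold_display)
  # the printed ratios were computed from unrounded fractions while the table
  # prints one decimal, so the printed ratio must lie inside the interval the
  # rounding permits: (num +/- 0.05) / (den -/+ 0.05)
  for (g in names(printed)[!is.na(printed)]) {
    i <- match(g, fc$gene)
    if (fc$denominator[i] <= 0.05) next
    lo <- (fc$numerator[i] - 0.05) / (fc$denominator[i] + 0.05)
    hi <- (fc$numerator[i] + 0.05) / (fc$denominator[i] - 0.05)
    expect_gte(printed[[g]] + 0.051, lo)
    expect_lte(printed[[g]] - 0.051, hi)
  }
  # lower-bound markers appear exactly when the denominator prints as zero
  lb <- startsWith(t5$fold_display, ">")
  expect_true(all(fc$denominator[match(names(t5$fold_display)[lb],
                                       fc$gene)] == 0))
})

test_that("enrichment flags require the focal fraction to dominate by the factor", {
  f <- matrix(c(20, 4, 3, 1,
                20, 6, 3, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("HIT", "MISS"), c("focal", "b", "c", "d")))
  dt <- detection_table(f)
  flagged <- enrichment_flags(dt, "focal", factor = 4)
  expect_true("HIT" %in% flagged)    # 20 >= 4 * 5? no: 20 >= 16
  expect_false("MISS" %in% flagged)  # 20 < 4 * 6
  # factor 1 reduces to at-least-highest (strict highest union ties)
  all1 <- enrichment_flags(dt, "focal", factor = 1)
  expect_setequal(all1, c("HIT", "MISS"))
})

test_that("cross-dataset algebra reproduces the printed shared and injury-private counts", {
  inj <- expressed_sets(nerve_table2())$any_type
  uninj <- expressed_sets(nerve_table3())$any_type
  neo <- expressed_sets(nerve_table4())$any_type
  expect_length(inj, 143)
  expect_length(uninj, 122)
  expect_length(neo, 119)
  cd <- cross_dataset_sets(list(injured = inj, uninjured = uninj,
                                neonatal = neo), injured = "injured")
  expect_equal(cd$regions$counts[["injured&uninjured&neonatal"]], 111)
  expect_length(cd$injured_only, 13)
  expect_setequal(cd$injured_only,
                  c("ARTN", "BTC", "CCL25", "CRLF1", "FGF5", "GDNF", "GNRH1",
                    "HGF", "RSPO3", "SEMA4F", "SHH", "TNFSF8", "UCN2"))
  # inclusion-exclusion: 143 - |union of the other two within the panel|
  expect_equal(143 - length(intersect(inj, union(uninj, neo))), 13)
})
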