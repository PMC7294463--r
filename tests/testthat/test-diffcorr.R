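test_that("mock bulks are per-gene means on the chosen normalization", {
  m <- matrix(c(0L, 2L, 4L, 0L, 1L, 5L), nrow = 3)  # 3 genes x 2 cells
  dge <- toy_dge(m)
  annot <- toy_annot(colnames(dge$counts), "t", datasets = "d1")
  mb <- mock_bulk(dge, annot, "d1", normalization = "none")
  expect_equal(unname(mb$profile), c(0, 1.5, 4.5))
  # a one-cell dataset's bulk is that cell's own profile
  annot1 <- annot; annot1$dataset <- c("solo", "other")
  solo <- mock_bulk(dge, annot1, "solo", normalization = "none")
  expect_equal(unname(solo$profile), c(0, 2, 4))
  expect_error(mock_bulk(dge, annot, "ghost"), "empty dataset")
})

test_that("mock bulk equals an explicit per-gene loop on simulated data", {
  cfg <- sim_config(c(tA = 100), sprintf("G%d", 1:15), detect_prob = 0.6,
                    seed = 23)
  sim <- simulate_dge(cfg)
  mb <- mock_bulk(sim$dge, sim$annot, "batch1")
  m <- nerveLR:::normalize_counts(sim$dge$counts, "library-size")
  loop <- vapply(rownames(m), function(g) mean(m[g, ]), numeric(1))
  expect_equal(mb$profile, loop)
})

test_that("correlations hit the perfect and inverse limits", {
  # dataset bulkA = cell c1's profile; c3 is an affine negation of it
  m <- cbind(c1 = c(1L, 2L, 3L, 4L, 5L), c2 = c(5L, 4L, 3L, 2L, 1L),
             c3 = c(5L, 4L, 3L, 2L, 1L))
  dge <- toy_dge(m, cells = colnames(m))
  annot <- toy_annot(colnames(m), "t", datasets = c("A", "B", "B"))
  bulks <- list(mock_bulk(dge, annot, "A", "none"),
                mock_bulk(dge, annot, "B", "none"))
  r <- correlate_cells(dge, bulks, normalization = "none")
  expect_equal(r["c1", "A"], 1)
  expect_equal(r["c2", "A"], -1)
  expect_true(all(r >= -1 & r <= 1))
})

test_that("Pearson r matches the textbook formula on a 5-gene example", {
  x <- c(2, 4, 4, 4, 6)
  y <- c(1, 2, 3, 5, 9)
  m <- cbind(cell = as.integer(x), ref = as.integer(y))
  dge <- toy_dge(m, cells = colnames(m))
  annot <- toy_annot(colnames(m), "t", datasets = c("q", "bulk"))
  r <- correlate_cells(dge, list(mock_bulk(dge, annot, "bulk", "none")),
                       normalization = "none")
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(r["cell", "bulk"]), hand)
})

test_that("zero-variance cells are flagged and excluded, constant bulks rejected", {
  m <- cbind(c1 = c(1L, 2L, 3L), c2 = c(2L, 2L, 2L), c3 = c(3L, 1L, 2L))
  dge <- toy_dge(m, cells = colnames(m))
  annot <- toy_annot(colnames(m), "t", datasets = c("A", "A", "A"))
  b <- mock_bulk(dge, annot, "A", "none")
  expect_warning(r <- correlate_cells(dge, list(b), normalization = "none"),
                 "zero-variance")
  expect_equal(attr(r, "flagged_cells"), "c2")
  expect_false("c2" %in% rownames(r))
  const <- b; const$profile[] <- 1
  expect_error(correlate_cells(dge, list(const), normalization = "none"),
               "constant")
})

test_that("differential coordinates are antisymmetric and zero at equidistance", {
  r <- matrix(c(0.8, 0.8, 0.2,
                0.5, 0.9, 0.1), nrow = 2, byrow = TRUE,
              dimnames = list(c("cellA", "cellB"), c("u", "n", "i")))
  dc <- differential_coordinates(r, x_pair = c("u", "n"),
                                 y_pair = c("u", "i"))
  expect_equal(dc$x[dc$cell_id == "cellA"], 0)
  swapped <- differential_coordinates(r, x_pair = c("n", "u"),
                                      y_pair = c("u", "i"))
  expect_equal(swapped$x, -dc$x)
  expect_equal(dc$y, r[, "u"] - r[, "i"], ignore_attr = TRUE)
  expect_true(all(abs(dc$x) <= 2 & abs(dc$y) <= 2))
  expect_error(differential_coordinates(r, c("u", "zz"), c("u", "i")),
               "unknown bulk")
})

test_that("correlations are invariant under positive affine rescaling of a bulk", {
  cfg <- sim_config(c(tA = 30), sprintf("G%d", 1:40), detect_prob = 0.5,
                    seed = 31)
  sim <- simulate_dge(cfg)
  b <- mock_bulk(sim$dge, sim$annot, "batch1")
  b_scaled <- b
  b_scaled$profile <- 3.7 * b$profile + 11
  r1 <- correlate_cells(sim$dge, list(b))
  r2 <- correlate_cells(sim$dge, list(b_scaled))
  expect_equal(unname(r1), unname(r2))
})

test_that("cells place on the correct side of the axis for their population of origin", {
  ng <- 2000
  set.seed(47)  # only for drawing the two probability profiles
  pA <- runif(ng, 0.02, 0.6)
  shift <- sample(ng, ng / 2)
  pB <- pA
  pB[shift] <- pmin(0.95, pA[shift] * 3 + 0.2)
  cfg <- sim_config(c(popA = 60, popB = 60), sprintf("G%04d", 1:ng),
                    detect_prob = cbind(popA = pA, popB = pB), seed = 53)
  sim <- simulate_dge(cfg)
  annot <- sim$annot
  annot$dataset <- annot$cell_type
  bulks <- list(mock_bulk(sim$dge, annot, "popA"),
                mock_bulk(sim$dge, annot, "popB"))
  r <- correlate_cells(sim$dge, bulks)
  dc <- differential_coordinates(r, c("popA", "popB"), c("popB", "popA"))
  from_a <- startsWith(dc$cell_id, "popA")
  expect_gte(mean(dc$x[from_a] > 0), 0.95)
  expect_gte(mean(dc$x[!from_a] < 0), 0.95)
  expect_gt(mean(dc$x[from_a]), 0)
})
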