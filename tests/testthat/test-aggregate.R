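test_that("delog inverts log1p exactly and enforces the scale contract", {
  x <- matrix(log1p(5), 1, 1, dimnames = list("g1", "c1"))
  attr(x, "scale") <- "lognorm"
  expect_equal(delog(x)[1, 1], 5, tolerance = 1e-12)

  z <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_equal(unname(delog(z, scale = "lognorm")), matrix(0, 2, 2),
               ignore_attr = TRUE)

  withr::with_seed(1, {
    raw <- matrix(rexp(60), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  })
  lg <- log1p(raw); attr(lg, "scale") <- "lognorm"
  expect_equal(unname(delog(lg)), unname(raw), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(attr(delog(lg), "scale"), "raw_counts")

  attr(raw, "scale") <- "raw_counts"
  expect_error(delog(raw), "log-normalized")
})

test_that("pseudo-bulk averages delogged expression per cell type", {
  raw <- matrix(c(2, 4, 6, 8,
                  1, 3, 5, 7), 2, 4, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  lg <- log1p(raw); attr(lg, "scale") <- "lognorm"
  labels <- c(c1 = "T1", c2 = "T1", c3 = "T2", c4 = "T2")
  pb <- pseudoBulk(lg, labels, dataset = "D")
  m <- SummarizedExperiment::assay(pb)
  expect_equal(m[, "T1"], c(g1 = 3, g2 = 2), tolerance = 1e-10)
  expect_equal(m[, "T2"], c(g1 = 7, g2 = 6), tolerance = 1e-10)
  expect_equal(profileKind(pb), "pseudo_bulk")

  # one cell per type: profile equals the delogged cell
  single <- pseudoBulk(with_scale(lg[, 1, drop = FALSE]), c(c1 = "T1"))
  expect_equal(SummarizedExperiment::assay(single)[, "T1"],
               raw[, 1], tolerance = 1e-10)

  # permutation invariance
  perm <- c(3, 1, 4, 2)
  pb2 <- pseudoBulk(with_scale(lg[, perm]), labels[perm], dataset = "D")
  expect_equal(SummarizedExperiment::assay(pb2), m)

  expect_error(pseudoBulk(lg, c(c1 = "T1")), "unlabeled")
})

test_that("pseudo-cell grouping follows the partition and leftover rules", {
  toy <- toy_lognorm(n_types = 2, cells_per_type = 25, seed = 3)
  pc <- pseudoCell(toy$mat, toy$labels, group_size = 10, seed = 5)
  cd <- SummarizedExperiment::colData(pc)
  # 25 cells -> 2 full groups, 5 dropped
  expect_equal(unname(table(cd$cell_type)), c(2L, 2L), ignore_attr = TRUE)
  expect_true(all(cd$n_cells == 10))

  # a type smaller than group_size keeps one undersized group
  small <- toy_lognorm(n_types = 2, cells_per_type = 7, seed = 3)
  pcs <- pseudoCell(small$mat, small$labels, group_size = 10, seed = 5)
  expect_equal(SummarizedExperiment::colData(pcs)$n_cells, c(7L, 7L))

  # exactly one full group: profile equals the type mean, seed-independent
  exact <- toy_lognorm(n_types = 1, cells_per_type = 10, seed = 2)
  p1 <- pseudoCell(exact$mat, exact$labels, group_size = 10, seed = 1)
  p2 <- pseudoCell(exact$mat, exact$labels, group_size = 10, seed = 77)
  bulk <- pseudoBulk(exact$mat, exact$labels)
  expect_equal(unname(SummarizedExperiment::assay(p1)),
               unname(SummarizedExperiment::assay(bulk)), tolerance = 1e-12)
  expect_equal(SummarizedExperiment::assay(p1),
               SummarizedExperiment::assay(p2))
})

test_that("pseudo-cell output is seed-deterministic with stable group sizes", {
  toy <- toy_lognorm(n_types = 3, cells_per_type = 23, seed = 8)
  a <- pseudoCell(toy$mat, toy$labels, seed = 42)
  b <- pseudoCell(toy$mat, toy$labels, seed = 42)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  c <- pseudoCell(toy$mat, toy$labels, seed = 43)
  expect_equal(sort(SummarizedExperiment::colData(a)$n_cells),
               sort(SummarizedExperiment::colData(c)$n_cells))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("pseudo-bulk equals pseudo-cell with group_size = type size", {
  toy <- toy_lognorm(n_types = 3, cells_per_type = 12, seed = 4)
  pb <- pseudoBulk(toy$mat, toy$labels, dataset = "D")
  pc <- pseudoCell(toy$mat, toy$labels, group_size = 12, seed = 9,
                   dataset = "D")
  a <- SummarizedExperiment::assay(pb)
  b <- SummarizedExperiment::assay(pc)
  colnames(b) <- SummarizedExperiment::colData(pc)$cell_type
  expect_equal(a, b[, colnames(a)], tolerance = 1e-12)
})

test_that("aggregation conserves totals: mean x group size = member sum", {
  toy <- toy_lognorm(n_types = 2, cells_per_type = 21, seed = 6)
  pc <- pseudoCell(toy$mat, toy$labels, group_size = 7, seed = 2)
  members <- S4Vectors::metadata(pc)$members
  xd <- delog(toy$mat)
  m <- SummarizedExperiment::assay(pc)
  for (j in seq_along(members)) {
    expect_equal(m[, j] * length(members[[j]]),
                 rowSums(xd[, members[[j]], drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("grouping never mixes libraries", {
  toy <- toy_lognorm(n_types = 1, cells_per_type = 40, seed = 6)
  libs <- rep(c("l1", "l2"), 20)
  pc <- pseudoCell(toy$mat, toy$labels, group_size = 10, seed = 3,
                   library_id = libs)
  members <- S4Vectors::metadata(pc)$members
  lib_of <- stats::setNames(libs, colnames(toy$mat))
  for (g in members) expect_length(unique(lib_of[g]), 1L)
})

test_that("Spearman matrix matches the definitional oracle", {
  withr::with_seed(10, {
    a <- matrix(rexp(20 * 4), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("p", 1:4)))
    b <- matrix(rexp(20 * 3), 20, 3,
                dimnames = list(paste0("g", 1:20), paste0("q", 1:3)))
  })
  pa <- make_profiles(log1p(a) |> structure(scale = "lognorm"),
                      colnames(a), "A")
  pb <- make_profiles(log1p(b) |> structure(scale = "lognorm"),
                      colnames(b), "B")
  sm <- scores(spearmanMatrix(pa, pb))
  for (i in 1:4) for (j in 1:3)
    expect_equal(sm[i, j], oracle_spearman(a[, i], b[, j]),
                 tolerance = 1e-12)

  # identical profiles correlate at 1; reversed ranks at -1
  v <- seq_len(20)
  c1 <- matrix(c(v, rev(v)), 20, 2,
               dimnames = list(paste0("g", 1:20), c("x", "y")))
  p1 <- make_profiles(log1p(c1) |> structure(scale = "lognorm"),
                      colnames(c1), "A")
  sm2 <- scores(spearmanMatrix(p1, p1))
  expect_equal(sm2["x", "x"], 1, tolerance = 1e-12)
  expect_equal(sm2["x", "y"], -1, tolerance = 1e-12)

  # invariance under a monotone transform of one side
  a2 <- a^3
  pa2 <- make_profiles(log1p(a2) |> structure(scale = "lognorm"),
                       colnames(a2), "A")
  expect_equal(scores(spearmanMatrix(pa2, pb)), sm, tolerance = 1e-12)
})

test_that("constant profiles yield NA Spearman entries with a warning", {
  m <- matrix(c(1:5, rep(2, 5)), 5, 2,
              dimnames = list(paste0("g", 1:5), c("ok", "flat")))
  p <- make_profiles(log1p(m) |> structure(scale = "lognorm"),
                     colnames(m), "A")
  expect_warning(sm <- spearmanMatrix(p, p), "constant")
  expect_true(is.na(scores(sm)["flat", "ok"]))
  expect_false(is.na(scores(sm)["ok", "ok"]))
})
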