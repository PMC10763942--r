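mk_scores <- function(m, metric = "auroc") {
  new("CellTypeScores", scores = m, metric = metric,
      trainDataset = "A", testDataset = "B")
}

two_by_two <- function(a11, e11, recip = FALSE) {
  A <- matrix(c(a11, 0.2, 0.3, 0.95), 2, 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("u", "v")))
  E <- matrix(c(e11, 0.1, 0.2, 0.9), 2, 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("u", "v")))
  hits <- if (recip)
    data.frame(train_type = c("x", "u"), test_type = c("u", "x"),
               score = a11, direction = c("a_to_b", "b_to_a"),
               reciprocal = TRUE)
  else data.frame(train_type = character(), test_type = character(),
                  score = numeric(), direction = character(),
                  reciprocal = logical())
  fuseScores(mk_scores(A), mk_scores(E, "enrichment_scaled"), hits = hits)
}

test_that("fusion averages the two arms and applies strict retention", {
  # auroc 0.9 + enrichment 0.7 -> 0.8, NOT retained without reciprocity
  cm <- two_by_two(0.9, 0.7)
  tb <- conservationTable(cm)
  row <- tb[tb$type_a == "x" & tb$type_b == "u", ]
  expect_equal(row$score, 0.8)
  expect_false(row$retained)
  # the same pair IS retained when reciprocal
  cm2 <- two_by_two(0.9, 0.7, recip = TRUE)
  expect_true(conservationTable(cm2)[1, "retained"])
  # perfect pair retained unconditionally
  cm3 <- two_by_two(1.0, 1.0)
  expect_true(conservationTable(cm3)[1, "retained"])
})

test_that("retention boundary: 0.79 / 0.80 / 0.81 with and without reciprocity", {
  for (s in c(0.79, 0.80, 0.81)) {
    plain <- conservationTable(two_by_two(s, s))[1, ]
    recip <- conservationTable(two_by_two(s, s, recip = TRUE))[1, ]
    expect_equal(plain$score, s)
    if (s > 0.80) expect_true(plain$retained)
    else expect_false(plain$retained)   # strict > 0.80
    expect_true(recip$retained)         # reciprocal always retained
  }
})

test_that("fusion is symmetric in its inputs and monotone in each score", {
  A <- matrix(runif(4, 0.3, 0.9), 2, 2,
              dimnames = list(c("x", "y"), c("u", "v")))
  E <- matrix(runif(4, 0.3, 0.9), 2, 2,
              dimnames = list(c("x", "y"), c("u", "v")))
  f1 <- conservationTable(fuseScores(mk_scores(A),
                                     mk_scores(E, "enrichment_scaled")))
  f2 <- conservationTable(fuseScores(mk_scores(E),
                                     mk_scores(A, "enrichment_scaled")))
  expect_equal(f1$score, f2$score)
  # raising either input never un-retains a retained pair
  cm <- two_by_two(0.85, 0.80)
  before <- conservationTable(cm)
  cm_up <- two_by_two(0.95, 0.80)
  after <- conservationTable(cm_up)
  retained_before <- paste(before$type_a, before$type_b)[before$retained]
  retained_after <- paste(after$type_a, after$type_b)[after$retained]
  expect_true(all(retained_before %in% retained_after))
})

test_that("pairs scored by one arm only are flagged partial", {
  A <- matrix(0.9, 1, 1, dimnames = list("x", "u"))
  E <- matrix(c(0.7, 0.6), 1, 2,
              dimnames = list("x", c("u", "w")))
  cm <- fuseScores(mk_scores(A), mk_scores(E, "enrichment_scaled"))
  tb <- conservationTable(cm)
  solo <- tb[tb$type_b == "w", ]
  expect_true(solo$partial)
  expect_equal(solo$score, 0.6)
  both <- tb[tb$type_b == "u", ]
  expect_false(both$partial)
  expect_equal(both$score, 0.8)
})

test_that("irreconcilable labels error and label maps reconcile them", {
  A <- matrix(0.9, 1, 1, dimnames = list("x", "u"))
  E <- matrix(0.7, 1, 1, dimnames = list("set_x", "u"))
  expect_error(fuseScores(mk_scores(A), mk_scores(E, "enrichment_scaled")),
               "set_x")
  cm <- fuseScores(mk_scores(A), mk_scores(E, "enrichment_scaled"),
                   label_map = list(a = c(set_x = "x")))
  expect_equal(conservationTable(cm)$score, 0.8)
})

test_that("rendered maps are deterministic, masked and counted correctly", {
  cm <- two_by_two(0.95, 0.95)
  out <- renderMap(cm)
  tb <- conservationTable(cm)
  expect_equal(nrow(out), sum(tb$retained))
  expect_true(all(diff(out$score) <= 0))
  low <- matrix(0.4, 2, 2, dimnames = list(c("x", "y"), c("u", "v")))
  none <- fuseScores(mk_scores(low), mk_scores(low, "enrichment_scaled"),
                     hits = data.frame(train_type = character(),
                                       test_type = character(),
                                       score = numeric(),
                                       direction = character(),
                                       reciprocal = logical()))
  expect_warning(empty <- renderMap(none), "no retained")
  expect_equal(nrow(empty), 0L)
  # random maps: row count equals retained count
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- matrix(runif(12, 0.2, 1), 3, 4,
                  dimnames = list(paste0("x", 1:3), paste0("u", 1:4)))
      E <- matrix(runif(12, 0, 1), 3, 4, dimnames = dimnames(A))
    })
    cmr <- fuseScores(mk_scores(A), mk_scores(E, "enrichment_scaled"),
                      hits = data.frame(train_type = character(),
                                        test_type = character(),
                                        score = numeric(),
                                        direction = character(),
                                        reciprocal = logical()))
    tbr <- conservationTable(cmr)
    if (sum(tbr$retained) > 0)
      expect_equal(nrow(renderMap(cmr)), sum(tbr$retained))
  }
})

test_that("truth metrics equal direct set arithmetic", {
  mk_cm <- function(pairs_a, pairs_b, retained) {
    tb <- S4Vectors::DataFrame(type_a = pairs_a, type_b = pairs_b,
                               auroc = 1, enrichment = 1, score = 1,
                               reciprocal = retained, partial = FALSE,
                               retained = retained)
    new("ConservationMap", table = tb, threshold = 0.8)
  }
  truth <- list(pairs = data.frame(type_a = c("p", "q"),
                                   type_b = c("P", "Q")))
  exact <- mk_cm(c("p", "q"), c("P", "Q"), c(TRUE, TRUE))
  tm <- truthMetrics(exact, truth)
  expect_equal(tm$precision, 1)
  expect_equal(tm$recall, 1)
  none <- mk_cm(c("p", "q"), c("P", "Q"), c(FALSE, FALSE))
  tm0 <- truthMetrics(none, truth)
  expect_equal(tm0$precision, 0)
  expect_equal(tm0$recall, 0)
  expect_true(tm0$empty_retained)
  # random retained sets vs set arithmetic
  for (seed in 1:5) {
    withr::with_seed(seed, {
      all_a <- paste0("t", 1:6); all_b <- paste0("T", 1:6)
      ret <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    })
    cm <- mk_cm(all_a, all_b, ret)
    tmx <- truthMetrics(cm, list(pairs = data.frame(type_a = all_a[1:3],
                                                    type_b = all_b[1:3])))
    tp <- sum(ret[1:3])
    expect_equal(tmx$recall, tp / 3)
    if (sum(ret)) expect_equal(tmx$precision, tp / sum(ret))
  }
})
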