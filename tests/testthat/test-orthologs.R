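empty_summary <- data.frame(gene = character(), mean_expr = numeric(),
                            n_detected = integer(), frac_detected = numeric())

test_that("single-candidate and precedence examples resolve as stated", {
  ea <- expr_summary_of("a1")
  eb <- expr_summary_of(c("b1", "b2"))

  # single candidate
  m <- resolveOrthologs(
    data.frame(gene_a = "a1", gene_b = "b1", weighted_score = 5,
               best_score_reverse = "Yes"), ea, eb)
  expect_equal(genePairs(m)$gene_b, "b1")
  expect_equal(genePairs(m)$rule, "unique")

  # score beats reverse flag
  m <- resolveOrthologs(
    data.frame(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
               weighted_score = c(9, 2),
               best_score_reverse = c(FALSE, TRUE)), ea, eb)
  expect_equal(genePairs(m)$gene_b, "b1")
  expect_equal(genePairs(m)$rule, "score")

  # reverse flag breaks score tie
  m <- resolveOrthologs(
    data.frame(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
               weighted_score = c(5, 5),
               best_score_reverse = c(FALSE, TRUE)), ea, eb)
  expect_equal(genePairs(m)$gene_b, "b2")
  expect_equal(genePairs(m)$rule, "reverse")

  # expression breaks score+reverse tie
  eb2 <- data.frame(gene = c("b1", "b2"), mean_expr = c(1, 3),
                    n_detected = c(5L, 5L), frac_detected = c(0.5, 0.5))
  m <- resolveOrthologs(
    data.frame(gene_a = c("a1", "a1"), gene_b = c("b1", "b2"),
               weighted_score = c(5, 5),
               best_score_reverse = c(TRUE, TRUE)), ea, eb2)
  expect_equal(genePairs(m)$gene_b, "b2")
  expect_equal(genePairs(m)$rule, "expression")
})

test_that("invalid candidate tables are rejected", {
  ea <- expr_summary_of("a1"); eb <- expr_summary_of("b1")
  expect_error(resolveOrthologs(
    data.frame(gene_a = "a1", gene_b = "b1", weighted_score = -1,
               best_score_reverse = TRUE), ea, eb), "non-negative")
  expect_error(resolveOrthologs(
    data.frame(gene_a = c("a1", "a1"), gene_b = c("b1", "b1"),
               weighted_score = c(1, 2),
               best_score_reverse = c(TRUE, FALSE)), ea, eb), "duplicate")
  expect_error(resolveOrthologs(
    data.frame(gene_a = character(), gene_b = character(),
               weighted_score = numeric(), best_score_reverse = logical()),
    ea, eb), "empty")
})

test_that("random many-to-many tables match the naive precedence oracle", {
  for (seed in 1:12) {
    inst <- random_candidates(seed)
    got <- genePairs(resolveOrthologs(inst$cand, inst$ea, inst$eb))
    want <- oracle_resolve(inst$cand, inst$ea, inst$eb)
    expect_equal(got[, c("gene_a", "gene_b")], want,
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("resolution is one-to-one, order-independent and deterministic", {
  inst <- random_candidates(99)
  m1 <- resolveOrthologs(inst$cand, inst$ea, inst$eb)
  p1 <- genePairs(m1)
  expect_false(anyDuplicated(p1$gene_a) > 0)
  expect_false(anyDuplicated(p1$gene_b) > 0)
  shuffled <- inst$cand[rev(seq_len(nrow(inst$cand))), ]
  p2 <- genePairs(resolveOrthologs(shuffled, inst$ea, inst$eb))
  expect_identical(p1, p2)
})

test_that("raising a retained pair's weighted score never removes it", {
  inst <- random_candidates(7)
  p <- genePairs(resolveOrthologs(inst$cand, inst$ea, inst$eb))
  for (i in c(1L, nrow(p) %/% 2L, nrow(p))) {
    cand2 <- inst$cand
    hit <- cand2$gene_a == p$gene_a[i] & cand2$gene_b == p$gene_b[i]
    cand2$weighted_score[hit] <- cand2$weighted_score[hit] + 10
    p2 <- genePairs(resolveOrthologs(cand2, inst$ea, inst$eb))
    expect_true(any(p2$gene_a == p$gene_a[i] & p2$gene_b == p$gene_b[i]))
  }
})

test_that("expressed-ortholog filtering follows detection counts", {
  ea <- data.frame(gene = c("a1", "a2"), mean_expr = c(1, 2),
                   n_detected = c(5L, 3L), frac_detected = c(0.5, 0.3))
  eb <- data.frame(gene = c("b1", "b2"), mean_expr = c(1, 2),
                   n_detected = c(0L, 4L), frac_detected = c(0, 0.4))
  m <- resolveOrthologs(
    data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
               weighted_score = c(5, 5),
               best_score_reverse = c(TRUE, TRUE)), ea, eb)
  # b1 undetected -> pair dropped
  f <- expressedOrthologs(m, ea, eb, min_cells = 1)
  expect_equal(genePairs(f)$gene_a, "a2")
  # all detected at min_cells = 3 -> a2/b2 retained; at 4, a2 side fails
  expect_equal(nrow(genePairs(expressedOrthologs(m, ea, eb, 3))), 1L)
  expect_equal(nrow(genePairs(expressedOrthologs(m, ea, eb, 4))), 0L)
  expect_error(expressedOrthologs(m, ea, eb, 0), "positive")

  # randomized masks equal a direct set filter
  for (seed in 1:5) {
    inst <- random_candidates(seed, n_a = 20, n_b = 20, max_cand = 3)
    mm <- resolveOrthologs(inst$cand, inst$ea, inst$eb)
    kept <- genePairs(expressedOrthologs(mm, inst$ea, inst$eb, 5))
    pp <- genePairs(mm)
    na <- inst$ea$n_detected[match(pp$gene_a, inst$ea$gene)]
    nb <- inst$eb$n_detected[match(pp$gene_b, inst$eb$gene)]
    expect_identical(kept, pp[na >= 5 & nb >= 5, ],
                     ignore_attr = TRUE)
  }
})

test_that("core orthologs are the intersection of species-A genes", {
  mk_map <- function(a, b) {
    new("OrthologMap",
        pairs = S4Vectors::DataFrame(gene_a = a, gene_b = b,
                                     rule = rep("unique", length(a)),
                                     weighted_score = rep(1, length(a))))
  }
  m1 <- mk_map(c("a1", "a2", "a3"), c("x1", "x2", "x3"))
  m2 <- mk_map(c("a2", "a3", "a4"), c("y1", "y2", "y3"))
  m3 <- mk_map(c("a3", "a5"), c("z1", "z2"))
  expect_equal(coreOrthologs(list(m1, m1)), c("a1", "a2", "a3"))
  expect_equal(coreOrthologs(list(m1, m2, m3)), "a3")
  m4 <- mk_map("a9", "w1")
  expect_equal(coreOrthologs(list(m1, m4)), character(0))
  expect_error(coreOrthologs(list(m1)), ">= 2")
})

test_that("ortholog tables round-trip through TSV files", {
  inst <- random_candidates(3)
  tf <- tempfile(fileext = ".tsv")
  cand <- inst$cand
  cand$best_score_reverse <- ifelse(cand$best_score_reverse, "Yes", "No")
  utils::write.table(cand, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- readOrthologCandidates(tf)
  expect_equal(nrow(rt), nrow(inst$cand))
  expect_type(rt$best_score_reverse, "logical")
  m <- resolveOrthologs(rt, inst$ea, inst$eb)
  out <- tempfile(fileext = ".tsv")
  writeOrthologMap(m, out)
  back <- utils::read.delim(out)
  expect_equal(back$gene_a, genePairs(m)$gene_a)
  expect_equal(back$rule_applied, genePairs(m)$rule)
})
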