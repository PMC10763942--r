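# Independent, naive reference implementations used to check the package's
# vectorized code. Written as plain loops, deliberately avoiding the code
# paths under test.

.o_lookup <- function(summary, g, what) {
  i <- match(g, summary$gene)
  if (is.na(i)) return(0)
  summary[[what]][i]
}

# Per-A-gene precedence choice: highest score, then reverse flag, then mean
# partner expression, then detection fraction, then alphabetical partner id.
.o_choose <- function(df, eb) {
  best <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    a <- df[best, ]; b <- df[i, ]
    keys_a <- c(a$weighted_score, a$best_score_reverse,
                .o_lookup(eb, a$gene_b, "mean_expr"),
                .o_lookup(eb, a$gene_b, "frac_detected"))
    keys_b <- c(b$weighted_score, b$best_score_reverse,
                .o_lookup(eb, b$gene_b, "mean_expr"),
                .o_lookup(eb, b$gene_b, "frac_detected"))
    swap <- FALSE
    for (k in seq_along(keys_a)) {
      if (keys_b[k] > keys_a[k]) { swap <- TRUE; break }
      if (keys_b[k] < keys_a[k]) break
      if (k == length(keys_a)) swap <- b$gene_b < a$gene_b
    }
    if (swap) best <- i
  }
  df[best, , drop = FALSE]
}

oracle_resolve <- function(cand, ea, eb) {
  if (is.character(cand$best_score_reverse))
    cand$best_score_reverse <- cand$best_score_reverse == "Yes"
  remaining <- split(cand, cand$gene_a)
  repeat {
    chosen <- lapply(remaining, .o_choose, eb = eb)
    picks <- do.call(rbind, chosen)
    tab <- table(picks$gene_b)
    contested <- names(tab)[tab > 1]
    if (!length(contested)) break
    for (b in contested) {
      claimants <- picks[picks$gene_b == b, ]
      # winner: score desc, reverse desc, A-gene mean expr desc, frac desc,
      # alphabetical A gene
      win <- 1L
      for (i in seq_len(nrow(claimants))[-1]) {
        u <- claimants[win, ]; v <- claimants[i, ]
        ku <- c(u$weighted_score, u$best_score_reverse,
                .o_lookup(ea, u$gene_a, "mean_expr"),
                .o_lookup(ea, u$gene_a, "frac_detected"))
        kv <- c(v$weighted_score, v$best_score_reverse,
                .o_lookup(ea, v$gene_a, "mean_expr"),
                .o_lookup(ea, v$gene_a, "frac_detected"))
        swap <- FALSE
        for (k in seq_along(ku)) {
          if (kv[k] > ku[k]) { swap <- TRUE; break }
          if (kv[k] < ku[k]) break
          if (k == length(ku)) swap <- v$gene_a < u$gene_a
        }
        if (swap) win <- i
      }
      losers <- claimants$gene_a[-win]
      for (a in losers) {
        r <- remaining[[a]]
        r <- r[!(r$gene_b == b), , drop = FALSE]
        if (nrow(r) == 0L) remaining[[a]] <- NULL else remaining[[a]] <- r
      }
    }
  }
  picks <- picks[order(picks$gene_a), c("gene_a", "gene_b"), drop = FALSE]
  rownames(picks) <- NULL
  picks
}

# Mann-Whitney AUROC by concordant-pair counting, ties 0.5
oracle_auroc <- function(values, positive) {
  pos <- values[positive]; neg <- values[!positive]
  tot <- 0
  for (u in pos) for (v in neg)
    tot <- tot + (u > v) + 0.5 * (u == v)
  tot / (length(pos) * length(neg))
}

# definitional Spearman: midranks by counting, explicit Pearson formula
oracle_spearman <- function(x, y) {
  rk <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  a <- rk(x); b <- rk(y)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# step-by-step gene-set variation statistic: kernel CDF -> symmetric ranks ->
# weighted KS random walk, signed sum of extreme deviations
oracle_gsva <- function(X, sets, tau = 1) {
  p <- nrow(X); n <- ncol(X)
  Z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    bw <- sd(X[i, ]) / 4
    for (j in seq_len(n))
      Z[i, j] <- mean(pnorm((X[i, j] - X[i, ]) / bw))
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(n)) {
    z <- Z[, j]
    s <- abs(rank(z) - (p + 1) / 2)^tau
    ord <- order(z, decreasing = TRUE)
    for (k in seq_along(sets)) {
      inset <- rownames(X) %in% sets[[k]]
      m <- sum(inset)
      sumw <- sum(s[inset])
      cur <- 0; mx <- 0; mn <- 0
      for (g in ord) {
        if (inset[g]) cur <- cur + s[g] / sumw
        else cur <- cur - 1 / (p - m)
        if (cur > mx) mx <- cur
        if (cur < mn) mn <- cur
      }
      out[k, j] <- mx + mn
    }
  }
  out
}

# full neighbor-voting AUROC path, loops + pair counting
oracle_auroc_matrix <- function(network, labels) {
  ds <- sort(unique(labels$dataset))
  res <- list()
  for (orient in 1:2) {
    train_ds <- ds[orient]; test_ds <- ds[3 - orient]
    tr <- which(labels$dataset == train_ds)
    te <- which(labels$dataset == test_ds)
    tt <- sort(unique(labels$cell_type[tr]))
    st <- sort(unique(labels$cell_type[te]))
    M <- matrix(NA_real_, length(tt), length(st), dimnames = list(tt, st))
    for (t in tt) {
      votes <- numeric(length(te))
      for (jj in seq_along(te)) {
        j <- te[jj]
        num <- sum(network[tr[labels$cell_type[tr] == t], j])
        votes[jj] <- num / sum(network[tr, j])
      }
      for (s in st) {
        pos <- labels$cell_type[te] == s
        if (sum(pos) >= 2 && sum(!pos) >= 1)
          M[t, s] <- oracle_auroc(votes, pos)
      }
    }
    res[[orient]] <- M
  }
  m1 <- res[[1]]; m2 <- t(res[[2]])
  out <- m1
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    v <- c(m1[i, j], m2[i, j])
    out[i, j] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

# argmax / reciprocal-best-hit oracle over a score matrix
oracle_top_hits <- function(s, threshold) {
  hits <- list()
  for (r in rownames(s)) {
    v <- s[r, ]
    if (all(is.na(v))) next
    b <- names(v)[which.max(v)]
    if (v[b] >= threshold) {
      w <- s[, b]
      rec <- !all(is.na(w)) && rownames(s)[which.max(w)] == r
      hits[[length(hits) + 1]] <- data.frame(train_type = r, test_type = b,
                                             score = unname(v[b]),
                                             reciprocal = rec)
    }
  }
  for (cc in colnames(s)) {
    w <- s[, cc]
    if (all(is.na(w))) next
    r <- rownames(s)[which.max(w)]
    if (w[r] >= threshold) {
      v <- s[r, ]
      rec <- !all(is.na(v)) && colnames(s)[which.max(v)] == cc
      hits[[length(hits) + 1]] <- data.frame(train_type = cc, test_type = r,
                                             score = unname(w[r]),
                                             reciprocal = rec)
    }
  }
  if (!length(hits)) return(data.frame(train_type = character(),
                                       test_type = character(),
                                       score = numeric(),
                                       reciprocal = logical()))
  do.call(rbind, hits)
}
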