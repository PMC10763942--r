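#' Select variable genes shared across datasets
#'
#' Per dataset, genes are binned into deciles of their median expression
#' across profiles; within each bin the genes in the top variance quartile
#' (and with non-zero variance) are kept. The returned list is the
#' intersection of the per-dataset selections, so a gene constant in any
#' dataset is never selected.
#'
#' @param profiles_list List of \linkS4class{PseudoProfiles} (>= 2), each
#'   with >= 3 profiles, on a shared gene universe.
#' @param n_bins Number of expression bins (default 10).
#' @param var_quantile Variance quantile defining the top slice per bin
#'   (default 0.75).
#' @return Character vector of selected gene ids (>= 10, else an error).
#' @export
selectVariableGenes <- function(profiles_list, n_bins = 10L,
                                var_quantile = 0.75) {
  stopifnot(is.list(profiles_list), length(profiles_list) >= 2L)
  sel <- lapply(profiles_list, function(pp) {
    stopifnot(is(pp, "PseudoProfiles"))
    m <- SummarizedExperiment::assay(pp)
    if (ncol(m) < 3L) stop("each dataset needs >= 3 profiles")
    med <- apply(m, 1, stats::median)
    v <- apply(m, 1, stats::var)
    breaks <- unique(stats::quantile(med, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(breaks) > 2L)
      cut(med, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    else rep(1L, length(med))
    keep <- unlist(lapply(split(seq_along(v), bin), function(ii) {
      thr <- stats::quantile(v[ii], var_quantile)
      ii[v[ii] >= thr & v[ii] > 0]
    }), use.names = FALSE)
    rownames(m)[keep]
  })
  genes <- sort(Reduce(intersect, sel))
  if (length(genes) < 10L)
    stop("fewer than 10 variable genes shared across datasets (got ",
         length(genes), ")")
  genes
}

#' Rank-normalized correlation network over merged profiles
#'
#' Spearman-correlates every profile pair of a merged (two-dataset) profile
#' matrix over the given genes, then rank-transforms each column (midranks)
#' and scales to (0, 1] by dividing by the number of profiles — the voting
#' network of the neighbor-voting step.
#'
#' @param profiles Merged \linkS4class{PseudoProfiles}
#'   (see [mergeProfiles()]).
#' @param genes Genes to use (e.g. from [selectVariableGenes()]); default
#'   all genes.
#' @return Square numeric matrix (profiles x profiles), columns scaled
#'   midranks of Spearman correlations.
#' @export
votingNetwork <- function(profiles, genes = NULL) {
  stopifnot(is(profiles, "PseudoProfiles"))
  m <- SummarizedExperiment::assay(profiles)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) stop("genes absent from profiles: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  const <- apply(m, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    stop("constant profile(s): ", paste(colnames(m)[const], collapse = ", "))
  rk <- apply(m, 2, .midrank)
  net <- stats::cor(rk, method = "pearson")
  apply(net, 2, function(v) .midrank(v) / length(v))
}

# Mann-Whitney AUROC from midranks: (R+ - P(P+1)/2) / (P * N)
.rank_auroc <- function(values, positive) {
  P <- sum(positive); N <- sum(!positive)
  if (P < 2L || N < 1L) return(NA_real_)
  r <- .midrank(values)
  (sum(r[positive]) - P * (P + 1) / 2) / (P * N)
}

#' Neighbor-voting AUROC matrix between two datasets
#'
#' For each train cell type in one dataset, every profile of the other
#' dataset receives a vote: the summed network similarity to the train
#' type's profiles, normalized by its total similarity to all train-dataset
#' profiles. The AUROC of each test type then measures how well votes rank
#' that type's profiles above the rest (Mann-Whitney midrank formula).
#' Both train/test orientations are computed and averaged where both exist;
#' test types with fewer than 2 profiles are undefined (\code{NA}) in that
#' orientation.
#'
#' @param network Voting network from [votingNetwork()].
#' @param labels \code{data.frame} with columns \code{dataset} (exactly 2
#'   levels) and \code{cell_type}, one row per network profile (in order),
#'   or a merged \linkS4class{PseudoProfiles} to take them from.
#' @return A \linkS4class{CellTypeScores} with metric \code{"auroc"}: rows
#'   are first-dataset cell types, columns second-dataset cell types.
#' @export
aurocMatrix <- function(network, labels) {
  if (is(labels, "PseudoProfiles"))
    labels <- as.data.frame(SummarizedExperiment::colData(labels))
  stopifnot(is.matrix(network), nrow(network) == ncol(network),
            nrow(labels) == nrow(network),
            all(c("dataset", "cell_type") %in% colnames(labels)))
  ds <- sort(unique(as.character(labels$dataset)))
  if (length(ds) != 2L) stop("exactly 2 datasets required, got ", length(ds))
  types <- lapply(ds, function(d)
    sort(unique(labels$cell_type[labels$dataset == d])))
  names(types) <- ds

  one_orientation <- function(train_ds, test_ds) {
    tr <- labels$dataset == train_ds
    te <- labels$dataset == test_ds
    denom <- colSums(network[tr, te, drop = FALSE])
    M <- matrix(NA_real_, length(types[[train_ds]]), length(types[[test_ds]]),
                dimnames = list(types[[train_ds]], types[[test_ds]]))
    te_type <- labels$cell_type[te]
    for (t in types[[train_ds]]) {
      votes <- colSums(network[tr & labels$cell_type == t, te, drop = FALSE]) /
        denom
      for (s in types[[test_ds]])
        M[t, s] <- .rank_auroc(votes, te_type == s)
    }
    M
  }
  m1 <- one_orientation(ds[1], ds[2])          # rows ds1 types, cols ds2
  m2 <- t(one_orientation(ds[2], ds[1]))       # transposed to same shape
  both <- !is.na(m1) & !is.na(m2)
  fused <- m1
  fused[both] <- (m1[both] + m2[both]) / 2
  fused[is.na(m1) & !is.na(m2)] <- m2[is.na(m1) & !is.na(m2)]
  new("CellTypeScores", scores = fused, metric = "auroc",
      trainDataset = ds[1], testDataset = ds[2])
}

#' Thresholded best hits and reciprocal best hits
#'
#' For each train cell type the best-scoring test type with AUROC at or
#' above the threshold is reported (both orientations). A pair is reciprocal
#' iff each member is the other's best-scoring match.
#'
#' @param score_matrix A \linkS4class{CellTypeScores} (typically AUROCs).
#' @param threshold Minimum score, in (0.5, 1]; comparison is inclusive.
#' @return \code{data.frame} with columns \code{train_type},
#'   \code{test_type}, \code{score}, \code{direction}, \code{reciprocal},
#'   ordered by score (descending).
#' @export
topHits <- function(score_matrix, threshold = 0.80) {
  stopifnot(is(score_matrix, "CellTypeScores"))
  if (length(threshold) != 1L || threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  s <- score_matrix@scores
  best_col <- apply(s, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  best_row <- apply(s, 2, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  recip <- function(r, c) !is.na(best_col[r]) && !is.na(best_row[c]) &&
    best_col[r] == c && best_row[c] == r
  rows <- list()
  for (r in seq_len(nrow(s))) {
    c <- best_col[r]
    if (!is.na(c) && s[r, c] >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        train_type = rownames(s)[r], test_type = colnames(s)[c],
        score = s[r, c], direction = "a_to_b",
        reciprocal = recip(r, c), stringsAsFactors = FALSE)
  }
  for (c in seq_len(ncol(s))) {
    r <- best_row[c]
    if (!is.na(r) && s[r, c] >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        train_type = colnames(s)[c], test_type = rownames(s)[r],
        score = s[r, c], direction = "b_to_a",
        reciprocal = recip(r, c), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(train_type = character(), test_type = character(),
                  score = numeric(), direction = character(),
                  reciprocal = logical(), stringsAsFactors = FALSE)
  out[order(-out$score, out$train_type), , drop = FALSE]
}
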