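#' Discover per-cell-type marker genes (one-vs-rest rank-sum)
#'
#' For every cell type, each gene is tested with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie correction and continuity
#' correction) of that type's cells against all other cells. Genes are kept
#' as markers when the effect is positive (higher in the focal type), the
#' gene is detected in at least \code{min_pct} of focal cells, and the
#' Bonferroni-adjusted p-value is at most \code{alpha}. Genes that qualify
#' as markers of more than one cell type are then excluded entirely — a
#' guard against genes tracking shared or continuously differentiating
#' states rather than a single identity.
#'
#' @param x Log-normalized expression matrix (genes x cells).
#' @param labels Cell-type label per cell.
#' @param min_pct Minimum detection fraction in the focal type
#'   (default 0.25).
#' @param alpha Adjusted p-value cutoff (default 0.05).
#' @return A \linkS4class{MarkerCatalog}; per type, genes are ordered by
#'   adjusted p-value, then effect size (log2 fold change of mean delogged
#'   expression, with a pseudo-count of 1).
#' @export
findMarkerGenes <- function(x, labels, min_pct = 0.25, alpha = 0.05) {
  x <- .as_expression_matrix(x)
  labels <- .check_labels(x, labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need >= 2 cell types")
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("cell types with < 3 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need >= 2 cell types with >= 3 cells")
  n <- ncol(x); G <- nrow(x)
  R <- t(apply(x, 1, .midrank))
  tie_term <- apply(x, 1, function(v) {
    tt <- table(v); sum(tt^3 - tt)
  })
  xd <- .delogged(structure(x, scale = "lognorm"))
  det <- x > 0
  res <- list()
  for (t in types) {
    focal <- labels == t
    n1 <- sum(focal); n2 <- n - n1
    W <- rowSums(R[, focal, drop = FALSE])
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    d <- W - mu
    d <- d - sign(d) * 0.5                    # continuity correction
    z <- ifelse(sigma2 > 0, d / sqrt(sigma2), 0)
    p <- ifelse(sigma2 > 0, 2 * stats::pnorm(-abs(z)), 1)
    p_adj <- pmin(1, p * G)
    mean_in <- rowMeans(xd[, focal, drop = FALSE])
    mean_out <- rowMeans(xd[, !focal, drop = FALSE])
    effect <- log2(mean_in + 1) - log2(mean_out + 1)
    pct <- rowMeans(det[, focal, drop = FALSE])
    keep <- effect > 0 & pct >= min_pct & p_adj <= alpha
    if (any(keep)) {
      df <- data.frame(cell_type = t, gene = rownames(x)[keep],
                       effect = effect[keep], p_adj = p_adj[keep],
                       pct_expressing = pct[keep], stringsAsFactors = FALSE)
      res[[t]] <- df[order(df$p_adj, -df$effect, df$gene), , drop = FALSE]
    }
  }
  tb <- if (length(res)) do.call(rbind, res)
  else data.frame(cell_type = character(), gene = character(),
                  effect = numeric(), p_adj = numeric(),
                  pct_expressing = numeric(), stringsAsFactors = FALSE)
  multi <- unique(tb$gene[duplicated(tb$gene)])
  tb <- tb[!tb$gene %in% multi, , drop = FALSE]
  rownames(tb) <- NULL
  new("MarkerCatalog", table = S4Vectors::DataFrame(tb))
}

#' Translate a marker catalog through an ortholog map
#'
#' Replaces species-A gene ids with their one-to-one species-B orthologs.
#' Genes without an ortholog are dropped; per-type set sizes before and
#' after translation are recorded in the \code{"translation"} attribute of
#' the returned catalog's table.
#'
#' @param catalog A \linkS4class{MarkerCatalog} in species-A gene ids.
#' @param map An \linkS4class{OrthologMap} (gene_a = species A).
#' @return A \linkS4class{MarkerCatalog} in species-B gene ids.
#' @export
translateMarkers <- function(catalog, map) {
  stopifnot(is(catalog, "MarkerCatalog"), is(map, "OrthologMap"))
  tb <- as.data.frame(catalog@table)
  m <- match(tb$gene, map@pairs$gene_a)
  before <- table(factor(tb$cell_type, levels = unique(tb$cell_type)))
  tb2 <- tb[!is.na(m), , drop = FALSE]
  tb2$gene <- map@pairs$gene_b[m[!is.na(m)]]
  after <- table(factor(tb2$cell_type, levels = names(before)))
  if (nrow(tb2) == 0L)
    warning("no marker gene has an ortholog; translated catalog is empty")
  out <- new("MarkerCatalog", table = S4Vectors::DataFrame(tb2))
  S4Vectors::metadata(out@table)$translation <-
    data.frame(cell_type = names(before), n_before = as.integer(before),
               n_after = as.integer(after), stringsAsFactors = FALSE)
  out
}
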