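#' Gene-set variation scores of marker sets in pseudo-bulk profiles
#'
#' Rank-based per-sample enrichment of each marker set, computed as:
#' (i) per gene, a Gaussian-kernel cumulative density estimate across
#' samples (bandwidth = per-gene sample SD / 4); (ii) per sample, genes are
#' ranked by this statistic and converted to symmetric rank scores
#' \eqn{|r - (p+1)/2|}, so both tails of the expression distribution carry
#' high weight; (iii) a weighted Kolmogorov-Smirnov random walk (weight
#' exponent \code{tau} = 1) down the genes ordered by decreasing statistic;
#' (iv) the enrichment score is the signed sum of the maximum positive and
#' maximum negative deviations of the walk, bounded in [-1, 1].
#'
#' Genes constant across samples (kernel bandwidth 0) are dropped with a
#' warning; sets with fewer than \code{min_set_size} genes present in the
#' profile matrix are dropped with a warning. Genes absent from the profiles
#' never influence a set's score.
#'
#' @param profiles \linkS4class{PseudoProfiles} (pseudo-bulk, >= 3 profiles).
#' @param catalog A \linkS4class{MarkerCatalog} in the profiles' gene ids
#'   (see [translateMarkers()]), or a named list of gene-id vectors.
#' @param min_set_size Minimum genes per set present in the profiles
#'   (default 5).
#' @param tau Rank-weight exponent of the random walk (default 1).
#' @return A \linkS4class{CellTypeScores} with metric \code{"enrichment"}:
#'   rows are marker sets (source cell types), columns profiles.
#' @seealso [scaleScores()] for the 0-1 rescaling applied before fusion.
#' @export
enrichmentScores <- function(profiles, catalog, min_set_size = 5L, tau = 1) {
  stopifnot(is(profiles, "PseudoProfiles"))
  X <- SummarizedExperiment::assay(profiles)
  if (ncol(X) < 3L) stop("need >= 3 profiles (samples)")
  sets <- if (is(catalog, "MarkerCatalog")) markerSets(catalog)
  else catalog
  if (!length(sets)) stop("no marker sets supplied")

  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " gene(s) constant across samples dropped")
    X <- X[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- nrow(X); ns <- ncol(X)

  sets <- lapply(sets, function(g) intersect(unique(g), rownames(X)))
  small <- names(sets)[lengths(sets) < min_set_size]
  if (length(small)) {
    warning("marker sets with < ", min_set_size, " genes present dropped: ",
            paste(small, collapse = ", "))
    sets <- sets[lengths(sets) >= min_set_size]
  }
  if (!length(sets)) stop("no marker set has enough genes in the profiles")

  # Gaussian-kernel CDF estimate per gene across samples
  bw <- sds / 4
  Z <- matrix(0, p, ns, dimnames = dimnames(X))
  for (k in seq_len(ns))
    Z <- Z + stats::pnorm((X - X[, k]) / bw)
  Z <- Z / ns

  es <- matrix(NA_real_, length(sets), ns,
               dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(ns)) {
    z <- Z[, j]
    r <- .midrank(z)
    w <- abs(r - (p + 1) / 2)^tau
    ord <- order(-z)
    for (si in seq_along(sets)) {
      inset <- rownames(X)[ord] %in% sets[[si]]
      m <- sum(inset)
      wo <- w[ord]
      step <- ifelse(inset, wo / sum(wo[inset]), -1 / (p - m))
      dev <- cumsum(step)
      es[si, j] <- max(c(0, dev)) + min(c(0, dev))
    }
  }
  new("CellTypeScores", scores = es, metric = "enrichment",
      trainDataset = "marker_sets",
      testDataset = paste(unique(
        SummarizedExperiment::colData(profiles)$dataset), collapse = ","))
}

#' Min-max scale an enrichment matrix to [0, 1]
#'
#' Global scaling over the whole matrix: \code{(x - min) / (max - min)}.
#' Global (rather than per-row) scaling preserves between-set comparability,
#' which the fusion step relies on.
#'
#' @param score_matrix A \linkS4class{CellTypeScores}.
#' @return A \linkS4class{CellTypeScores} with metric suffix
#'   \code{"_scaled"}; values in [0, 1].
#' @export
scaleScores <- function(score_matrix) {
  stopifnot(is(score_matrix, "CellTypeScores"))
  s <- score_matrix@scores
  rng <- range(s, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("constant score matrix; scaled values set to 0.5")
    s[] <- 0.5
  } else {
    s <- (s - rng[1]) / (rng[2] - rng[1])
  }
  methods::initialize(score_matrix, scores = s,
                      metric = paste0(score_matrix@metric, "_scaled"))
}
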