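#' Summarize per-gene expression for ortholog resolution
#'
#' Computes, for every gene of an expression matrix, the mean delogged
#' expression across all cells and the number (and fraction) of cells with
#' non-zero expression. These summaries drive the expression-level tie-break
#' during ortholog resolution and the detection filter of
#' [expressedOrthologs()].
#'
#' @param x Numeric matrix, genes x cells. If \code{scale} (or the matrix's
#'   \code{"scale"} attribute) is \code{"lognorm"}, values are delogged with
#'   \code{expm1} before averaging.
#' @param scale \code{"raw_counts"} or \code{"lognorm"}; defaults to the
#'   matrix's \code{"scale"} attribute, else \code{"raw_counts"}.
#' @return A \code{data.frame} with columns \code{gene}, \code{mean_expr},
#'   \code{n_detected}, \code{frac_detected}.
#' @export
expressionSummary <- function(x, scale = NULL) {
  x <- .as_expression_matrix(x)
  if (is.null(scale)) scale <- attr(x, "scale") %||% "raw_counts"
  scale <- match.arg(scale, c("raw_counts", "lognorm"))
  if (scale == "lognorm") x <- .delog_values(x)
  data.frame(
    gene = rownames(x),
    mean_expr = rowMeans(x),
    n_detected = as.integer(rowSums(x > 0)),
    frac_detected = rowMeans(x > 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.validate_candidates <- function(candidates) {
  need <- c("gene_a", "gene_b", "weighted_score", "best_score_reverse")
  if (!is.data.frame(candidates) || !all(need %in% colnames(candidates)))
    stop("candidates must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  if (nrow(candidates) == 0L)
    stop("candidate table is empty")
  if (any(!is.finite(candidates$weighted_score)) ||
      any(candidates$weighted_score < 0))
    stop("weighted_score must be finite and non-negative")
  if (anyDuplicated(candidates[, c("gene_a", "gene_b")]))
    stop("duplicate (gene_a, gene_b) rows in candidate table")
  rev <- candidates$best_score_reverse
  if (is.character(rev)) rev <- rev %in% c("Yes", "yes", "TRUE", "true", "1")
  candidates$best_score_reverse <- as.logical(rev)
  candidates
}

.expr_lookup <- function(summary, genes) {
  m <- match(genes, summary$gene)
  list(mean = ifelse(is.na(m), 0, summary$mean_expr[m]),
       frac = ifelse(is.na(m), 0, summary$frac_detected[m]),
       n = ifelse(is.na(m), 0L, summary$n_detected[m]))
}

#' Resolve a many-to-many ortholog candidate table to a one-to-one map
#'
#' Applies, per species-A gene with several candidate partners, the
#' precedence rules (1) highest weighted score, (2) best-score-reverse flag,
#' (3) highest mean delogged expression of the partner gene (then detection
#' fraction, then lexicographic gene id). Remaining many-to-one collisions —
#' several A genes electing the same B gene — are resolved greedily in
#' descending (weighted score, reverse flag, mean expression of the A gene,
#' alphabetical gene id) order; losers fall back to their next-best
#' candidate, iterating to a fixpoint. The result is strictly one-to-one and
#' independent of input row order.
#'
#' @param candidates \code{data.frame} with columns \code{gene_a},
#'   \code{gene_b}, \code{weighted_score} (non-negative),
#'   \code{best_score_reverse} (logical or \code{"Yes"}/\code{"No"}).
#' @param expr_a,expr_b Expression summaries from [expressionSummary()] for
#'   species A and B; genes absent from a summary are treated as unexpressed.
#' @return An \linkS4class{OrthologMap}; the \code{rule} column records, per
#'   pair, which precedence level decided it (\code{unique}, \code{score},
#'   \code{reverse}, \code{expression}) or \code{global_greedy} for pairs
#'   installed during collision resolution.
#' @export
resolveOrthologs <- function(candidates, expr_a, expr_b) {
  cand <- .validate_candidates(candidates)
  ea <- .expr_lookup(expr_a, cand$gene_a)
  eb <- .expr_lookup(expr_b, cand$gene_b)
  cand$mean_a <- ea$mean; cand$frac_a <- ea$frac
  cand$mean_b <- eb$mean; cand$frac_b <- eb$frac

  # canonical order -> row-order independence
  cand <- cand[order(cand$gene_a, cand$gene_b), , drop = FALSE]

  # per-A-gene candidate ranking by the stated precedence
  split_idx <- split(seq_len(nrow(cand)), cand$gene_a)
  ranked <- lapply(split_idx, function(ii) {
    cc <- cand[ii, , drop = FALSE]
    ord <- order(-cc$weighted_score, -cc$best_score_reverse,
                 -cc$mean_b, -cc$frac_b, cc$gene_b)
    ii[ord]
  })

  .decide_rule <- function(ii) {
    if (length(ii) == 1L) return("unique")
    top <- cand[ii[1L], ]; second <- cand[ii[2L], ]
    if (top$weighted_score > second$weighted_score) return("score")
    if (top$best_score_reverse > second$best_score_reverse) return("reverse")
    "expression"
  }
  rules <- vapply(ranked, .decide_rule, character(1))

  # greedy fixpoint on B-side collisions; `pos` advances only forward
  pos <- stats::setNames(rep(1L, length(ranked)), names(ranked))
  fell_back <- stats::setNames(rep(FALSE, length(ranked)), names(ranked))
  repeat {
    active <- names(pos)[pos <= lengths(ranked)[names(pos)]]
    if (!length(active)) break
    pick <- vapply(active, function(a) ranked[[a]][pos[a]], integer(1))
    b_of <- cand$gene_b[pick]
    dup_b <- unique(b_of[duplicated(b_of)])
    if (!length(dup_b)) break
    for (b in dup_b) {
      claim <- active[b_of == b]
      rows <- pick[b_of == b]
      ord <- order(-cand$weighted_score[rows],
                   -cand$best_score_reverse[rows],
                   -cand$mean_a[rows], -cand$frac_a[rows],
                   cand$gene_a[rows])
      losers <- claim[ord[-1L]]
      pos[losers] <- pos[losers] + 1L
      fell_back[losers] <- TRUE
    }
  }

  keep_a <- names(pos)[pos <= lengths(ranked)[names(pos)]]
  rows <- vapply(keep_a, function(a) ranked[[a]][pos[a]], integer(1))
  out <- cand[rows, c("gene_a", "gene_b", "weighted_score"), drop = FALSE]
  out$rule <- ifelse(fell_back[keep_a], "global_greedy", rules[keep_a])
  out <- out[order(out$gene_a), , drop = FALSE]
  new("OrthologMap",
      pairs = S4Vectors::DataFrame(gene_a = out$gene_a, gene_b = out$gene_b,
                                   rule = out$rule,
                                   weighted_score = out$weighted_score))
}

#' Filter an ortholog map to pairs detected in both datasets
#'
#' Retains pairs whose genes are both expressed (non-zero in at least
#' \code{min_cells} cells) in their respective species' data.
#'
#' @param map An \linkS4class{OrthologMap}.
#' @param expr_a,expr_b Expression summaries ([expressionSummary()]).
#' @param min_cells Minimum number of cells with non-zero expression
#'   required on each side (default 1).
#' @return The filtered \linkS4class{OrthologMap} (still one-to-one).
#' @export
expressedOrthologs <- function(map, expr_a, expr_b, min_cells = 1L) {
  stopifnot(is(map, "OrthologMap"))
  if (length(min_cells) != 1L || is.na(min_cells) || min_cells < 1)
    stop("min_cells must be a positive integer")
  p <- map@pairs
  na <- .expr_lookup(expr_a, p$gene_a)$n
  nb <- .expr_lookup(expr_b, p$gene_b)$n
  keep <- na >= min_cells & nb >= min_cells
  new("OrthologMap", pairs = p[keep, , drop = FALSE])
}

#' Species-A genes shared by several ortholog maps
#'
#' Intersects the species-A gene sets of two or more ortholog maps that
#' share the same species-A gene universe — the genes conserved (and, after
#' [expressedOrthologs()], expressed) in every partner species.
#'
#' @param maps A list of \linkS4class{OrthologMap} objects (length >= 2).
#' @return Character vector of species-A gene ids, sorted.
#' @export
coreOrthologs <- function(maps) {
  if (!is.list(maps) || length(maps) < 2L ||
      !all(vapply(maps, is, logical(1), "OrthologMap")))
    stop("maps must be a list of >= 2 OrthologMap objects")
  sets <- lapply(maps, function(m) m@pairs$gene_a)
  sort(Reduce(intersect, sets))
}

#' Read / write ortholog tables
#'
#' \code{readOrthologCandidates} reads a candidate TSV with header columns
#' \code{gene_a}, \code{gene_b}, \code{weighted_score},
#' \code{best_score_reverse} (Yes/No). \code{writeOrthologMap} writes a
#' resolved map as a TSV with columns \code{gene_a}, \code{gene_b},
#' \code{rule_applied}.
#'
#' @param path File path.
#' @param map An \linkS4class{OrthologMap}.
#' @return \code{readOrthologCandidates}: validated \code{data.frame};
#'   \code{writeOrthologMap}: \code{path}, invisibly.
#' @export
readOrthologCandidates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .validate_candidates(df)
}

#' @rdname readOrthologCandidates
#' @export
writeOrthologMap <- function(map, path) {
  stopifnot(is(map, "OrthologMap"))
  p <- as.data.frame(map@pairs)
  utils::write.table(
    data.frame(gene_a = p$gene_a, gene_b = p$gene_b, rule_applied = p$rule),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
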