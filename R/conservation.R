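#' Fuse AUROC and enrichment scores into a conservation map
#'
#' For every cross-species cell-type pair the conservation score is the
#' arithmetic mean of the neighbor-voting AUROC and the scaled enrichment
#' score; pairs scored by only one arm carry that value alone and are
#' flagged \code{partial}. A pair is retained when it is a reciprocal best
#' hit or its conservation score is strictly above the threshold.
#'
#' @param auroc A \linkS4class{CellTypeScores} with metric \code{"auroc"}
#'   (species-A types x species-B types).
#' @param enrichment A \linkS4class{CellTypeScores} of scaled enrichment
#'   scores (marker sets from species-A types x species-B types); see
#'   [scaleScores()].
#' @param hits Optional hit list from [topHits()] supplying reciprocal
#'   flags; computed from \code{auroc} at \code{auroc_threshold} when
#'   \code{NULL}.
#' @param threshold Retention threshold; strictly-greater comparison
#'   (default 0.80).
#' @param auroc_threshold Threshold for the internally computed hit list
#'   (default 0.80).
#' @param label_map Optional list with elements \code{a} and/or \code{b}:
#'   named character vectors renaming enrichment row/column labels to the
#'   AUROC matrix's labels.
#' @return A \linkS4class{ConservationMap}.
#' @export
fuseScores <- function(auroc, enrichment, hits = NULL, threshold = 0.80,
                       auroc_threshold = 0.80, label_map = NULL) {
  stopifnot(is(auroc, "CellTypeScores"), is(enrichment, "CellTypeScores"))
  A <- auroc@scores
  E <- enrichment@scores
  if (!is.null(label_map)) {
    if (!is.null(label_map$a))
      rownames(E) <- ifelse(rownames(E) %in% names(label_map$a),
                            label_map$a[rownames(E)], rownames(E))
    if (!is.null(label_map$b))
      colnames(E) <- ifelse(colnames(E) %in% names(label_map$b),
                            label_map$b[colnames(E)], colnames(E))
  }
  if (!length(intersect(rownames(A), rownames(E))) ||
      !length(intersect(colnames(A), colnames(E))))
    stop("labels irreconcilable between matrices; orphans: ",
         paste(unique(c(setdiff(rownames(E), rownames(A)),
                        setdiff(colnames(E), colnames(A)))), collapse = ", "))
  if (is.null(hits)) hits <- topHits(auroc, auroc_threshold)
  recip_keys <- unique(unlist(
    lapply(which(hits$reciprocal), function(i)
      paste(hits$train_type[i], hits$test_type[i], sep = "\r"))))
  # reciprocal hits are emitted in both orientations; normalize to A->B keys
  rows <- sort(unique(c(rownames(A), rownames(E))))
  cols <- sort(unique(c(colnames(A), colnames(E))))
  rec <- list()
  for (a in rows) for (b in cols) {
    va <- if (a %in% rownames(A) && b %in% colnames(A)) A[a, b] else NA_real_
    ve <- if (a %in% rownames(E) && b %in% colnames(E)) E[a, b] else NA_real_
    if (is.na(va) && is.na(ve)) next
    sc <- mean(c(va, ve), na.rm = TRUE)
    reciprocal <- paste(a, b, sep = "\r") %in% recip_keys ||
      paste(b, a, sep = "\r") %in% recip_keys
    rec[[length(rec) + 1L]] <- data.frame(
      type_a = a, type_b = b, auroc = va, enrichment = ve, score = sc,
      reciprocal = reciprocal, partial = is.na(va) || is.na(ve),
      retained = reciprocal || sc > threshold, stringsAsFactors = FALSE)
  }
  tb <- if (length(rec)) do.call(rbind, rec)
  else data.frame(type_a = character(), type_b = character(),
                  auroc = numeric(), enrichment = numeric(),
                  score = numeric(), reciprocal = logical(),
                  partial = logical(), retained = logical(),
                  stringsAsFactors = FALSE)
  new("ConservationMap", table = S4Vectors::DataFrame(tb),
      threshold = threshold)
}

#' Long-format table (and optional heatmap) of retained pairs
#'
#' Emits the retained pairs of a conservation map as a deterministic
#' long-format table, ordered by score (descending, ties broken by type
#' labels). Non-retained pairs are masked (excluded).
#'
#' @param map A \linkS4class{ConservationMap}.
#' @param plot If \code{TRUE} and the \pkg{pheatmap} package is installed,
#'   also draw a heatmap of retained scores.
#' @return \code{data.frame} with columns \code{type_a}, \code{type_b},
#'   \code{score}, \code{reciprocal}; empty (with a warning) when nothing
#'   is retained.
#' @export
renderMap <- function(map, plot = FALSE) {
  stopifnot(is(map, "ConservationMap"))
  tb <- as.data.frame(map@table)
  if (nrow(tb) == 0L) stop("conservation map is empty")
  tb <- tb[tb$retained, c("type_a", "type_b", "score", "reciprocal"),
           drop = FALSE]
  if (nrow(tb) == 0L) {
    warning("no retained pairs to render")
    return(tb)
  }
  tb <- tb[order(-tb$score, tb$type_a, tb$type_b), , drop = FALSE]
  rownames(tb) <- NULL
  if (plot && requireNamespace("pheatmap", quietly = TRUE)) {
    m <- matrix(NA_real_, length(unique(tb$type_a)), length(unique(tb$type_b)),
                dimnames = list(sort(unique(tb$type_a)),
                                sort(unique(tb$type_b))))
    for (i in seq_len(nrow(tb))) m[tb$type_a[i], tb$type_b[i]] <- tb$score[i]
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       na_col = "grey90")
  }
  tb
}

#' Write a conservation map as CSV
#'
#' @param map A \linkS4class{ConservationMap}.
#' @param path Output file.
#' @param species_a,species_b Species tags written alongside the type
#'   labels.
#' @return \code{path}, invisibly.
#' @export
writeConservationMap <- function(map, path, species_a = "species_a",
                                 species_b = "species_b") {
  stopifnot(is(map, "ConservationMap"))
  tb <- as.data.frame(map@table)
  out <- data.frame(species_a = species_a, type_a = tb$type_a,
                    species_b = species_b, type_b = tb$type_b,
                    auroc = tb$auroc, enrichment = tb$enrichment,
                    score = tb$score, reciprocal = tb$reciprocal,
                    retained = tb$retained)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
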