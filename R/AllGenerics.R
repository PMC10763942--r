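#' Accessors for scHomology classes
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x An object of the matching class.
#' @return \code{genePairs} returns a \code{data.frame} of resolved pairs;
#'   \code{profileKind} the aggregation kind; \code{scores} the numeric score
#'   matrix; \code{metricName} its metric label; \code{markerTable} and
#'   \code{conservationTable} plain \code{data.frame}s; \code{markerSets} a
#'   named list of gene vectors per cell type; \code{retainedPairs} the
#'   retained subset of a conservation map.
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genePairs", function(x) standardGeneric("genePairs"))

#' @rdname accessors
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))

#' @rdname accessors
#' @export
setGeneric("conservationTable", function(x) standardGeneric("conservationTable"))

#' @rdname accessors
#' @export
setGeneric("retainedPairs", function(x) standardGeneric("retainedPairs"))

#' @rdname accessors
#' @export
setMethod("genePairs", "OrthologMap", function(x) as.data.frame(x@pairs))

#' @rdname accessors
#' @export
setMethod("profileKind", "PseudoProfiles", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("scores", "CellTypeScores", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("metricName", "CellTypeScores", function(x) x@metric)

#' @rdname accessors
#' @export
setMethod("markerTable", "MarkerCatalog", function(x) as.data.frame(x@table))

#' @rdname accessors
#' @export
setMethod("markerSets", "MarkerCatalog", function(x) {
  tb <- as.data.frame(x@table)
  split(tb$gene, factor(tb$cell_type, levels = unique(tb$cell_type)))
})

#' @rdname accessors
#' @export
setMethod("conservationTable", "ConservationMap",
          function(x) as.data.frame(x@table))

#' @rdname accessors
#' @export
setMethod("retainedPairs", "ConservationMap", function(x) {
  tb <- as.data.frame(x@table)
  tb[tb$retained, , drop = FALSE]
})

setMethod("show", "OrthologMap", function(object) {
  p <- object@pairs
  cat("OrthologMap with", nrow(p), "one-to-one gene pairs\n")
  if (nrow(p)) {
    cat("  rules:", paste(sprintf("%s=%d", names(table(p$rule)),
                                  as.integer(table(p$rule))), collapse = " "),
        "\n")
  }
})

setMethod("show", "PseudoProfiles", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PseudoProfiles [", object@kind, "]: ", nrow(object), " genes x ",
      ncol(object), " profiles\n", sep = "")
  cat("  datasets:", paste(unique(cd$dataset), collapse = ", "), "\n")
  cat("  cell types:", length(unique(cd$cell_type)), "\n")
})

setMethod("show", "CellTypeScores", function(object) {
  cat("CellTypeScores [", object@metric, "]: ",
      nrow(object@scores), " train x ", ncol(object@scores),
      " test cell types (", object@trainDataset, " -> ",
      object@testDataset, ")\n", sep = "")
})

setMethod("show", "MarkerCatalog", function(object) {
  tb <- object@table
  cat("MarkerCatalog:", nrow(tb), "marker genes across",
      length(unique(tb$cell_type)), "cell types\n")
})

setMethod("show", "ConservationMap", function(object) {
  tb <- object@table
  cat("ConservationMap:", nrow(tb), "scored pairs,",
      sum(tb$retained), "retained (threshold >",
      format(object@threshold), "or reciprocal)\n")
})
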