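#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.ORTHOLOG_RULES <- c("unique", "score", "reverse", "expression", "global_greedy")

#' One-to-one ortholog map between two species
#'
#' Holds resolved gene pairs between a species-A and a species-B gene
#' universe. The map is strictly one-to-one: no gene identifier occurs twice
#' on either side. Each pair records the precedence rule that selected it.
#'
#' @slot pairs A \linkS4class{DataFrame} with columns \code{gene_a},
#'   \code{gene_b}, \code{rule} (one of \code{unique}, \code{score},
#'   \code{reverse}, \code{expression}, \code{global_greedy}) and
#'   \code{weighted_score}.
#'
#' @seealso [resolveOrthologs()], [expressedOrthologs()], [coreOrthologs()]
#' @export
setClass("OrthologMap", representation(pairs = "DataFrame"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "rule", "weighted_score")
  if (!all(need %in% colnames(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$gene_a))
    return("gene_a identifiers are not unique (map must be one-to-one)")
  if (anyDuplicated(p$gene_b))
    return("gene_b identifiers are not unique (map must be one-to-one)")
  if (!all(p$rule %in% .ORTHOLOG_RULES))
    return(paste("rule must be one of:", paste(.ORTHOLOG_RULES, collapse = ", ")))
  TRUE
})

#' Pseudo-bulk / pseudo-cell profile container
#'
#' A \linkS4class{SummarizedExperiment} holding aggregated expression
#' profiles (genes x profiles) on the delogged (raw) scale. Column metadata
#' carries the source cell type, the dataset/species tag, and the number of
#' member cells per profile.
#'
#' @slot kind Either \code{"pseudo_bulk"} (one profile per cell type) or
#'   \code{"pseudo_cell"} (random disjoint groups within each cell type).
#'
#' @seealso [pseudoBulk()], [pseudoCell()]
#' @export
setClass("PseudoProfiles",
         contains = "SummarizedExperiment",
         representation(kind = "character"))

setValidity("PseudoProfiles", function(object) {
  if (length(object@kind) != 1L ||
      !object@kind %in% c("pseudo_bulk", "pseudo_cell"))
    return("kind must be 'pseudo_bulk' or 'pseudo_cell'")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_type", "dataset", "n_cells")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  a <- SummarizedExperiment::assay(object)
  if (any(!is.finite(a)) || any(a < 0))
    return("profile values must be finite and non-negative")
  TRUE
})

#' Cell-type x cell-type score matrix
#'
#' A real-valued matrix scoring every (train cell type, test cell type) pair
#' between two datasets, with orientation metadata. Used for neighbor-voting
#' AUROCs, Spearman correlations, and scaled enrichment scores.
#'
#' @slot scores Numeric matrix; rows are train-side cell types, columns
#'   test-side cell types. \code{NA} marks undefined entries.
#' @slot metric Short label, e.g. \code{"auroc"}, \code{"spearman"},
#'   \code{"enrichment"}, \code{"enrichment_scaled"}.
#' @slot trainDataset,testDataset Dataset/species tags for the two axes.
#'
#' @export
setClass("CellTypeScores",
         representation(scores = "matrix", metric = "character",
                        trainDataset = "character", testDataset = "character"))

setValidity("CellTypeScores", function(object) {
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("scores must have row and column names")
  if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
    return("row/column labels must be unique")
  if (identical(object@metric, "auroc")) {
    v <- s[is.finite(s)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return("AUROC values must lie in [0, 1]")
  }
  TRUE
})

#' Per-cell-type marker gene catalog
#'
#' For each cell type, the signature genes surviving the marker filters
#' (positive effect, minimum detection fraction, adjusted p-value cutoff,
#' and exclusion of genes marking more than one type), ordered by adjusted
#' p-value then effect size.
#'
#' @slot table A \linkS4class{DataFrame} with columns \code{cell_type},
#'   \code{gene}, \code{effect}, \code{p_adj}, \code{pct_expressing}.
#'
#' @seealso [findMarkerGenes()], [translateMarkers()]
#' @export
setClass("MarkerCatalog", representation(table = "DataFrame"))

setValidity("MarkerCatalog", function(object) {
  tb <- object@table
  need <- c("cell_type", "gene", "effect", "p_adj", "pct_expressing")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb) && anyDuplicated(tb$gene))
    return("a gene appears under more than one cell type (catalogs must be disjoint)")
  TRUE
})

#' Cross-species cell-type conservation map
#'
#' Records every scored (species-A type, species-B type) pair with its
#' neighbor-voting AUROC, scaled enrichment score, fused conservation score
#' (the mean of the two when both exist), reciprocal-best-hit flag, and the
#' retention decision (reciprocal OR conservation score strictly above the
#' retention threshold).
#'
#' @slot table A \linkS4class{DataFrame} with columns \code{type_a},
#'   \code{type_b}, \code{auroc}, \code{enrichment}, \code{score},
#'   \code{reciprocal}, \code{partial}, \code{retained}.
#' @slot threshold The retention threshold applied (default 0.80).
#'
#' @seealso [fuseScores()], [renderMap()], [truthMetrics()]
#' @export
setClass("ConservationMap",
         representation(table = "DataFrame", threshold = "numeric"))

setValidity("ConservationMap", function(object) {
  tb <- object@table
  need <- c("type_a", "type_b", "auroc", "enrichment", "score",
            "reciprocal", "partial", "retained")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1L || is.na(object@threshold))
    return("threshold must be a single number")
  TRUE
})
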