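#' Library-size normalize and log-transform raw counts
#'
#' Scales each cell to \code{scale_factor} total counts and applies
#' \code{log1p}. The result carries the \code{"lognorm"} scale flag expected
#' by [delog()] and the aggregation functions.
#'
#' @param counts Raw count matrix, genes x cells.
#' @param scale_factor Target library size (default 1e4).
#' @return Matrix with attribute \code{scale = "lognorm"}.
#' @export
logNormalize <- function(counts, scale_factor = 1e4) {
  counts <- .as_expression_matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("cells with zero total counts: ",
                          paste(utils::head(colnames(counts)[lib == 0], 5),
                                collapse = ", "))
  out <- log1p(sweep(counts, 2, scale_factor / lib, `*`))
  attr(out, "scale") <- "lognorm"
  out
}

#' Invert log1p-normalized expression
#'
#' Antilogs a log-normalized matrix (elementwise \code{exp(x) - 1}, clipped
#' at zero to absorb rounding), recovering the normalized raw scale on which
#' pseudo-bulk and pseudo-cell averaging operate.
#'
#' @param x Matrix whose \code{"scale"} attribute is \code{"lognorm"}, or
#'   with \code{scale = "lognorm"} given explicitly.
#' @param scale Scale flag override; applying delog to raw counts is an
#'   error.
#' @return Matrix with attribute \code{scale = "raw_counts"}.
#' @export
delog <- function(x, scale = NULL) {
  x <- .as_expression_matrix(x)
  if (is.null(scale)) scale <- attr(x, "scale")
  if (is.null(scale))
    stop("matrix has no 'scale' attribute; pass scale = \"lognorm\"")
  if (!identical(scale, "lognorm"))
    stop("delog expects log-normalized input (scale = \"lognorm\"), got: ",
         scale)
  out <- .delog_values(x)
  attr(out, "scale") <- "raw_counts"
  out
}

# mean of delogged expression over the given cell columns
.delogged <- function(x) {
  sc <- attr(x, "scale") %||% "raw_counts"
  if (sc == "lognorm") .delog_values(x) else x
}

.new_profiles <- function(mat, meta, kind) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profiles = mat),
    colData = S4Vectors::DataFrame(meta, row.names = colnames(mat)))
  new("PseudoProfiles", se, kind = kind)
}

#' Pseudo-bulk profiles per cell type
#'
#' Averages delogged expression over all cells of each cell type, producing
#' one profile per type.
#'
#' @param x Expression matrix (genes x cells); log-normalized input is
#'   delogged before averaging.
#' @param labels Cell-type label per cell (named by cell id, or in column
#'   order).
#' @param dataset Dataset/species tag stored in the profile metadata.
#' @return A \linkS4class{PseudoProfiles} of kind \code{"pseudo_bulk"};
#'   profile columns are named by cell type.
#' @export
pseudoBulk <- function(x, labels, dataset = "dataset") {
  x <- .as_expression_matrix(x)
  labels <- .check_labels(x, labels)
  xd <- .delogged(x)
  types <- sort(unique(labels))
  prof <- vapply(types, function(t)
    rowMeans(xd[, labels == t, drop = FALSE]), numeric(nrow(xd)))
  dimnames(prof) <- list(rownames(xd), types)
  members <- split(colnames(x), labels)[types]
  pp <- .new_profiles(prof,
                      data.frame(cell_type = types, dataset = dataset,
                                 n_cells = lengths(members)),
                      "pseudo_bulk")
  S4Vectors::metadata(pp)$members <- members
  pp
}

#' Pseudo-cell profiles: random groups within each cell type
#'
#' Within each (library, cell type) stratum, cells are partitioned into
#' disjoint random groups of \code{group_size} (sampling without
#' replacement, seeded); each profile is the per-gene mean of delogged
#' expression over its group. Leftover cells short of a full group are
#' dropped, unless a stratum holds fewer than \code{group_size} cells in
#' total, in which case one undersized group keeps the whole stratum.
#'
#' @param x Expression matrix (genes x cells).
#' @param labels Cell-type label per cell.
#' @param group_size Cells per pseudo-cell (default 10).
#' @param seed Integer seed; grouping is fully reproducible.
#' @param dataset Dataset/species tag.
#' @param library_id Optional per-cell library id; grouping never mixes
#'   libraries.
#' @return A \linkS4class{PseudoProfiles} of kind \code{"pseudo_cell"}.
#' @export
pseudoCell <- function(x, labels, group_size = 10L, seed = 1L,
                       dataset = "dataset", library_id = NULL) {
  x <- .as_expression_matrix(x)
  labels <- .check_labels(x, labels)
  if (length(group_size) != 1L || group_size < 1) stop("group_size must be >= 1")
  lib <- if (is.null(library_id)) rep("lib1", ncol(x))
         else rep_len(as.character(library_id), ncol(x))
  xd <- .delogged(x)
  strata <- split(seq_len(ncol(x)), list(lib, labels), drop = TRUE, sep = "\r")
  strata <- strata[order(names(strata))]
  groups <- withr::with_seed(seed, {
    lapply(strata, function(ii) {
      ii <- ii[sample.int(length(ii))]
      n <- length(ii)
      if (n < group_size) return(list(ii))
      k <- n %/% group_size
      split(ii[seq_len(k * group_size)], rep(seq_len(k), each = group_size))
    })
  })
  meta <- do.call(rbind, lapply(names(groups), function(s) {
    parts <- strsplit(s, "\r", fixed = TRUE)[[1L]]
    data.frame(cell_type = parts[2L], library = parts[1L],
               group = seq_along(groups[[s]]),
               n_cells = lengths(groups[[s]]), stringsAsFactors = FALSE)
  }))
  flat <- unlist(groups, recursive = FALSE, use.names = FALSE)
  prof <- vapply(flat, function(ii)
    rowMeans(xd[, ii, drop = FALSE]), numeric(nrow(xd)))
  dimnames(prof) <- list(rownames(xd),
                         sprintf("%s.%s.%s.g%d", dataset, meta$cell_type,
                                 meta$library, meta$group))
  pp <- .new_profiles(prof,
                      data.frame(cell_type = meta$cell_type, dataset = dataset,
                                 library = meta$library, n_cells = meta$n_cells),
                      "pseudo_cell")
  S4Vectors::metadata(pp)$members <- lapply(flat, function(ii) colnames(x)[ii])
  pp
}

#' Spearman correlation matrix between two profile sets
#'
#' Correlates every profile of A with every profile of B over a shared gene
#' list using Spearman rank correlation (midrank ties). Profiles constant
#' over the shared genes yield \code{NA} entries (with a warning).
#'
#' @param profiles_a,profiles_b \linkS4class{PseudoProfiles} objects.
#' @param genes Shared gene list; defaults to the intersection of row names.
#'   At least 3 genes are required.
#' @return A \linkS4class{CellTypeScores} with metric \code{"spearman"}:
#'   rows are A profiles, columns B profiles.
#' @export
spearmanMatrix <- function(profiles_a, profiles_b, genes = NULL) {
  stopifnot(is(profiles_a, "PseudoProfiles"), is(profiles_b, "PseudoProfiles"))
  ma <- SummarizedExperiment::assay(profiles_a)
  mb <- SummarizedExperiment::assay(profiles_b)
  if (is.null(genes)) genes <- intersect(rownames(ma), rownames(mb))
  if (length(genes) < 3L) stop("need >= 3 shared genes")
  ma <- ma[genes, , drop = FALSE]; mb <- mb[genes, , drop = FALSE]
  const_a <- apply(ma, 2, function(v) length(unique(v)) == 1L)
  const_b <- apply(mb, 2, function(v) length(unique(v)) == 1L)
  if (any(const_a) || any(const_b))
    warning("constant profiles over shared genes (entries set to NA): ",
            paste(c(colnames(ma)[const_a], colnames(mb)[const_b]),
                  collapse = ", "))
  rk <- function(m) apply(m, 2, .midrank)
  sc <- suppressWarnings(stats::cor(rk(ma), rk(mb), method = "pearson"))
  sc[const_a, ] <- NA_real_
  sc[, const_b] <- NA_real_
  new("CellTypeScores", scores = sc, metric = "spearman",
      trainDataset = unique(SummarizedExperiment::colData(profiles_a)$dataset),
      testDataset = unique(SummarizedExperiment::colData(profiles_b)$dataset))
}

#' Merge two species' profiles over an ortholog map
#'
#' Restricts species-A profiles to mapped A genes and species-B profiles to
#' the corresponding B genes, renames the B genes to their A orthologs, and
#' binds the profile columns into one matrix — the substrate of the
#' neighbor-voting network.
#'
#' @param profiles_a,profiles_b \linkS4class{PseudoProfiles}.
#' @param map An \linkS4class{OrthologMap} (gene_a in A's universe, gene_b
#'   in B's).
#' @return A \linkS4class{PseudoProfiles} over the shared ortholog genes
#'   (A ids), same kind as the inputs.
#' @export
mergeProfiles <- function(profiles_a, profiles_b, map) {
  stopifnot(is(profiles_a, "PseudoProfiles"), is(profiles_b, "PseudoProfiles"),
            is(map, "OrthologMap"))
  ma <- SummarizedExperiment::assay(profiles_a)
  mb <- SummarizedExperiment::assay(profiles_b)
  p <- as.data.frame(map@pairs)
  p <- p[p$gene_a %in% rownames(ma) & p$gene_b %in% rownames(mb), , drop = FALSE]
  if (nrow(p) < 3L) stop("fewer than 3 ortholog genes shared by the profiles")
  ma <- ma[p$gene_a, , drop = FALSE]
  mb <- mb[p$gene_b, , drop = FALSE]
  rownames(mb) <- p$gene_a
  cda <- SummarizedExperiment::colData(profiles_a)
  cdb <- SummarizedExperiment::colData(profiles_b)
  keep <- c("cell_type", "dataset", "n_cells")
  meta <- rbind(as.data.frame(cda[, keep]), as.data.frame(cdb[, keep]))
  .new_profiles(cbind(ma, mb), meta, profiles_a@kind)
}
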