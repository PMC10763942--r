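#' Read an expression matrix (MatrixMarket or dense CSV)
#'
#' Reads either a MatrixMarket triplet (\code{matrix.mtx} with sidecar
#' \code{genes.tsv} / \code{barcodes.tsv} in the same directory, or explicit
#' paths) or a dense CSV with gene ids in the first column and cell ids in
#' the header. The result is validated: unique gene and cell ids,
#' non-negative finite values.
#'
#' @param path Directory containing \code{matrix.mtx}, a \code{.mtx} file,
#'   or a \code{.csv} file.
#' @param genes,cells Optional explicit paths to the gene/cell id files
#'   (one id per line, first column used) for MTX input.
#' @param scale Scale flag to attach: \code{"raw_counts"} (default) or
#'   \code{"lognorm"}.
#' @return Dense numeric matrix, genes x cells, with a \code{"scale"}
#'   attribute.
#' @export
readExpression <- function(path, genes = NULL, cells = NULL,
                           scale = c("raw_counts", "lognorm")) {
  scale <- match.arg(scale)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes <- genes %||% file.path(path, "genes.tsv")
    cells <- cells %||% file.path(path, "barcodes.tsv")
    path <- mtx
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes) || is.null(cells))
      stop("MTX input needs gene and cell id files")
    m <- as.matrix(Matrix::readMM(path))
    gid <- utils::read.delim(genes, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
    cid <- utils::read.delim(cells, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
    if (length(gid) != nrow(m) || length(cid) != ncol(m))
      stop("dimension mismatch between matrix (", nrow(m), "x", ncol(m),
           ") and id files (", length(gid), ", ", length(cid), ")")
    dimnames(m) <- list(gid, cid)
  } else {
    df <- utils::read.csv(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
    m <- as.matrix(df)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  if (any(!is.finite(m))) stop("non-finite expression values")
  if (any(m < 0)) stop("negative expression values")
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix (MatrixMarket or dense CSV)
#'
#' @param x Matrix, genes x cells.
#' @param path Output \code{.mtx} file (sidecar \code{genes.tsv} and
#'   \code{barcodes.tsv} are written next to it) or \code{.csv} file.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
  x <- .as_expression_matrix(x)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(x), file.path(dirname(path), "barcodes.tsv"))
  } else {
    utils::write.csv(as.data.frame(x), path, quote = FALSE)
  }
  invisible(path)
}

# split a merged PseudoProfiles back into its per-dataset halves
.split_profiles <- function(merged) {
  cd <- SummarizedExperiment::colData(merged)
  lapply(split(seq_len(ncol(merged)), cd$dataset), function(ii) {
    new("PseudoProfiles", merged[, ii], kind = merged@kind)
  })
}

#' Run the full cross-species comparison on in-memory data
#'
#' Chains the pipeline stages: ortholog resolution and expression filtering,
#' log-normalization, pseudo-cell aggregation and the unsupervised
#' neighbor-voting AUROC arm, marker discovery / translation / pseudo-bulk
#' enrichment as the supervised arm, and fusion into a conservation map.
#' Marker sets come from species A (the "simpler" species) and are scored
#' on species B's pseudo-bulk profiles.
#'
#' @param counts_a,counts_b Raw count matrices (genes x cells).
#' @param labels_a,labels_b Cell-type labels (named by cell id).
#' @param candidates Ortholog candidate table (see [resolveOrthologs()]).
#' @param library_a,library_b Optional per-cell library ids.
#' @param group_size Pseudo-cell group size (default 10).
#' @param auroc_threshold Top-hit AUROC threshold: 0.75 for comparisons
#'   involving distant species pairs, 0.80 otherwise (default 0.80).
#' @param fuse_threshold Conservation retention threshold (default 0.80).
#' @param min_pct,alpha Marker filters (defaults 0.25, 0.05).
#' @param min_cells Detection filter for expressed orthologs (default 1).
#' @param seed Seed controlling pseudo-cell grouping.
#' @return List with \code{conservation} (\linkS4class{ConservationMap}),
#'   \code{ortholog_map}, \code{auroc}, \code{hits}, \code{markers},
#'   \code{enrichment} (scaled), and \code{variable_genes}.
#' @export
runCrossSpecies <- function(counts_a, labels_a, counts_b, labels_b,
                            candidates, library_a = NULL, library_b = NULL,
                            group_size = 10L, auroc_threshold = 0.80,
                            fuse_threshold = 0.80, min_pct = 0.25,
                            alpha = 0.05, min_cells = 1L, seed = 1L) {
  log_a <- logNormalize(counts_a)
  log_b <- logNormalize(counts_b)
  sum_a <- expressionSummary(log_a)
  sum_b <- expressionSummary(log_b)
  omap <- resolveOrthologs(candidates, sum_a, sum_b)
  omap <- expressedOrthologs(omap, sum_a, sum_b, min_cells = min_cells)

  pc_a <- pseudoCell(log_a, labels_a, group_size = group_size, seed = seed,
                     dataset = "A", library_id = library_a)
  pc_b <- pseudoCell(log_b, labels_b, group_size = group_size,
                     seed = seed + 1L, dataset = "B", library_id = library_b)
  merged <- mergeProfiles(pc_a, pc_b, omap)
  vg <- selectVariableGenes(.split_profiles(merged))
  net <- votingNetwork(merged, vg)
  auroc <- aurocMatrix(net, merged)
  hits <- topHits(auroc, auroc_threshold)

  markers <- findMarkerGenes(log_a, labels_a, min_pct = min_pct,
                             alpha = alpha)
  markers_b <- translateMarkers(markers, omap)
  pb_b <- pseudoBulk(log_b, labels_b, dataset = "B")
  enr <- scaleScores(enrichmentScores(pb_b, markers_b))
  cons <- fuseScores(auroc, enr, hits = hits, threshold = fuse_threshold)

  list(conservation = cons, ortholog_map = omap, auroc = auroc, hits = hits,
       markers = markers, enrichment = enr, variable_genes = vg)
}

#' Run the pipeline from a configuration (YAML or list)
#'
#' The configuration either carries a \code{simulate} block (arguments to
#' [simConfig()]) or file paths (\code{counts_a}, \code{labels_a},
#' \code{counts_b}, \code{labels_b}, \code{candidates}); a \code{params}
#' block passes through to [runCrossSpecies()], and an optional \code{qc}
#' block (thresholds per [qcThresholds()]) filters cells first. When
#' \code{out_dir} is set, stage artifacts (resolved ortholog map, AUROC and
#' enrichment CSVs, conservation CSV) and a JSON manifest of parameters,
#' seeds and artifact checksums are written.
#'
#' @param config List or path to a YAML file.
#' @return As [runCrossSpecies()], plus \code{manifest}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- config$params %||% list()
  if (!is.null(config$simulate)) {
    sim <- simulatePair(do.call(simConfig, config$simulate))
    dat <- sim[c("counts_a", "labels_a", "library_a",
                 "counts_b", "labels_b", "library_b", "candidates")]
  } else {
    for (f in c("counts_a", "labels_a", "counts_b", "labels_b", "candidates"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing input file for '", f, "': ",
             config[[f]] %||% "(not set)")
    read_labels <- function(p) {
      df <- utils::read.delim(p, header = TRUE, stringsAsFactors = FALSE)
      stats::setNames(df$cell_type, df$cell_id)
    }
    dat <- list(counts_a = readExpression(config$counts_a),
                labels_a = read_labels(config$labels_a),
                library_a = NULL,
                counts_b = readExpression(config$counts_b),
                labels_b = read_labels(config$labels_b),
                library_b = NULL,
                candidates = readOrthologCandidates(config$candidates))
  }
  if (!is.null(config$qc)) {
    th <- do.call(qcThresholds, config$qc)
    for (sp in c("a", "b")) {
      cm <- dat[[paste0("counts_", sp)]]
      lib <- dat[[paste0("library_", sp)]] %||% "lib1"
      qc <- applyQC(cellQCMetrics(cm, library_id = lib), th)
      keep <- colnames(cm) %in% qc$kept
      dat[[paste0("counts_", sp)]] <- cm[, keep, drop = FALSE]
      dat[[paste0("labels_", sp)]] <-
        dat[[paste0("labels_", sp)]][colnames(cm)[keep]]
      if (length(lib) > 1L) dat[[paste0("library_", sp)]] <- lib[keep]
    }
  }
  res <- do.call(runCrossSpecies, c(dat, params))

  manifest <- list(params = params, simulate = config$simulate,
                   seed = params$seed %||% 1L,
                   n_ortholog_pairs = nrow(res$ortholog_map@pairs),
                   n_variable_genes = length(res$variable_genes),
                   n_retained = sum(conservationTable(res$conservation)$retained))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    writeOrthologMap(res$ortholog_map, file.path(od, "ortholog_map.tsv"))
    utils::write.csv(scores(res$auroc), file.path(od, "auroc.csv"),
                     quote = FALSE)
    utils::write.csv(scores(res$enrichment), file.path(od, "enrichment.csv"),
                     quote = FALSE)
    writeConservationMap(res$conservation,
                         file.path(od, "conservation_map.csv"))
    files <- c("ortholog_map.tsv", "auroc.csv", "enrichment.csv",
               "conservation_map.csv")
    manifest$checksums <- as.list(tools::md5sum(file.path(od, files)))
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(res, list(manifest = manifest))
}
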