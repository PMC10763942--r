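#' Cell quality-control thresholds
#'
#' Bundle of per-library QC thresholds: a minimum detected-gene count, a
#' maximum mitochondrial fraction, an optional hard UMI cap, and the
#' standard-deviation multiplier for the UMI outlier rule (mean + k * SD,
#' default k = 2).
#'
#' @param min_genes Minimum detected genes per cell (default 200).
#' @param max_mito_fraction Maximum mitochondrial read fraction (default 0.1).
#' @param umi_cap Optional hard UMI ceiling (e.g. 50000); \code{NULL} disables.
#' @param sd_multiplier Multiplier k for the UMI mean + k * SD doublet rule.
#' @return A list of class \code{"QCThresholds"}.
#' @export
qcThresholds <- function(min_genes = 200L, max_mito_fraction = 0.1,
                         umi_cap = NULL, sd_multiplier = 2) {
  if (min_genes < 0) stop("min_genes must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0, 1]")
  if (!is.null(umi_cap) && (length(umi_cap) != 1L || umi_cap <= 0))
    stop("umi_cap must be a positive number or NULL")
  if (sd_multiplier <= 0) stop("sd_multiplier must be positive")
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_fraction = max_mito_fraction,
                 umi_cap = umi_cap, sd_multiplier = sd_multiplier),
            class = "QCThresholds")
}

#' Per-cell QC metrics from a count matrix
#'
#' @param counts Raw count matrix, genes x cells.
#' @param library_id Optional per-cell library/batch id (recycled if length 1).
#' @param mito_prefixes Gene-id prefixes identifying mitochondrial genes;
#'   default covers fly (\code{mt:}) and vertebrate (\code{mt-}, \code{MT-})
#'   nomenclature.
#' @return \code{data.frame} with columns \code{cell_id}, \code{umi},
#'   \code{genes}, \code{mito_frac}, \code{library}.
#' @export
cellQCMetrics <- function(counts, library_id = "lib1",
                          mito_prefixes = c("mt:", "mt-", "MT-")) {
  counts <- .as_expression_matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pat <- paste0("^(", paste(gsub("([][{}()+*^$|\\\\.?-])", "\\\\\\1",
                                 mito_prefixes), collapse = "|"), ")")
  is_mt <- grepl(pat, rownames(counts))
  umi <- colSums(counts)
  data.frame(
    cell_id = colnames(counts),
    umi = umi,
    genes = as.integer(colSums(counts > 0)),
    mito_frac = if (any(is_mt)) colSums(counts[is_mt, , drop = FALSE]) /
      pmax(umi, 1) else 0,
    library = rep_len(as.character(library_id), ncol(counts)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.apply_qc_one <- function(records, th) {
  reason <- rep(NA_character_, nrow(records))
  # rule 1: hard UMI cap
  if (!is.null(th$umi_cap))
    reason[is.na(reason) & records$umi > th$umi_cap] <- "umi_cap"
  # rule 2: UMI outliers, mean/SD on cells surviving the cap
  surv <- is.na(reason)
  if (sum(surv) >= 2L) {
    mu <- mean(records$umi[surv])
    sdev <- stats::sd(records$umi[surv])
    reason[surv & records$umi > mu + th$sd_multiplier * sdev] <- "umi_outlier"
  } else if (sum(surv) == 1L) {
    warning("library '", records$library[1],
            "': single cell after UMI cap; SD undefined, outlier rule skipped")
  }
  # rule 3: gene-count floor
  reason[is.na(reason) & records$genes < th$min_genes] <- "low_genes"
  # rule 4: mitochondrial ceiling
  reason[is.na(reason) & records$mito_frac > th$max_mito_fraction] <- "high_mito"
  reason
}

#' Apply per-library cell quality filters
#'
#' Removal rules fire in order: (1) hard UMI cap, (2) UMI above
#' mean + k * SD — mean and SD computed per library on cells surviving the
#' cap (a doublet/multiplet heuristic; note this rule is not idempotent:
#' re-applying it to survivors can remove further cells since the mean and
#' SD shrink), (3) detected genes below the floor, (4) mitochondrial
#' fraction above the ceiling. Each removed cell is attributed to the first
#' rule that fires.
#'
#' @param records Per-cell QC table from [cellQCMetrics()] (columns
#'   \code{cell_id}, \code{umi}, \code{genes}, \code{mito_frac}, and
#'   optionally \code{library}).
#' @param thresholds A [qcThresholds()] object, or a named list of them
#'   keyed by library id for per-library thresholds.
#' @return List with \code{kept} (cell ids), \code{removed} (named counts
#'   per rule), and \code{detail} (per-cell removal reason, \code{NA} if
#'   kept).
#' @export
applyQC <- function(records, thresholds) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  need <- c("cell_id", "umi", "genes", "mito_frac")
  if (!all(need %in% colnames(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.null(records$library)) records$library <- "lib1"
  per_lib <- !inherits(thresholds, "QCThresholds")
  if (per_lib && !all(unique(records$library) %in% names(thresholds)))
    stop("thresholds missing for libraries: ",
         paste(setdiff(unique(records$library), names(thresholds)),
               collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  for (lib in unique(records$library)) {
    ii <- which(records$library == lib)
    th <- if (per_lib) thresholds[[lib]] else thresholds
    reason[ii] <- .apply_qc_one(records[ii, , drop = FALSE], th)
  }
  rules <- c("umi_cap", "umi_outlier", "low_genes", "high_mito")
  removed <- vapply(rules, function(r) sum(reason == r, na.rm = TRUE),
                    integer(1))
  list(kept = records$cell_id[is.na(reason)],
       removed = removed,
       detail = data.frame(cell_id = records$cell_id, library = records$library,
                           removed_by = reason, stringsAsFactors = FALSE))
}
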