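#' Configuration for the two-species simulator
#'
#' Defines a pair of synthetic single-cell datasets with planted cell-type
#' homology. Each species carries \code{n_matched + 1} cell types: the
#' matched identities (shared latent expression programs, connected through
#' the true ortholog map) plus one species-specific type whose markers live
#' on private (non-orthologous) genes. The first two matched identities form
#' a progenitor -> differentiated continuum: the differentiated type
#' re-uses a fraction of the progenitor's markers at half effect.
#'
#' @param n_matched Number of matched (homologous) identities per species
#'   (default 5, giving 6 types per species with the species-specific one).
#' @param n_orthologs Orthologous genes shared by the species (default 3000).
#' @param n_private Private genes per species (default 300).
#' @param cells_per_type Cells per cell type (default 300).
#' @param markers_per_type Marker genes per type (default 50).
#' @param marker_lfc Natural-log fold change of marker genes in their type
#'   (default 1.5, roughly 4.5-fold).
#' @param continuum_share Fraction of progenitor markers re-expressed (at
#'   half effect) in the differentiated type (default 0.4).
#' @param spec_similarity Fraction of a matched identity's markers that the
#'   species-specific type co-expresses at half effect — a different
#'   identity in each species. This models the species-specific type as a
#'   derived specialist of a conserved lineage (in the way fly-only
#'   lamellocytes derive from the plasmatocyte lineage) rather than a
#'   wholly alien program (default 0.8).
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives Poisson
#'   counts, the noise-free limit (default 0.5).
#' @param frac_one_to_many Fraction of ortholog genes receiving decoy
#'   candidates in the candidate table (default 0.2).
#' @param tie_prob Probability a decoy ties the true pair's weighted score,
#'   exercising the reverse-flag and expression tie-breaks (default 0.1).
#' @param n_libraries Sequencing libraries per species (default 2).
#' @param library_depth Relative depth per library (default \code{c(1, 1.6)}).
#' @param depth_sdlog Log-normal SD of per-cell depth factors (default 0.3).
#' @param total_counts Target mean UMI per cell at depth 1 (default 4000).
#' @param seed Integer seed for the whole simulation.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_matched = 5L, n_orthologs = 3000L, n_private = 300L,
                      cells_per_type = 300L, markers_per_type = 50L,
                      marker_lfc = 1.5, continuum_share = 0.4,
                      spec_similarity = 0.8,
                      dispersion = 0.5, frac_one_to_many = 0.2,
                      tie_prob = 0.1, n_libraries = 2L,
                      library_depth = c(1, 1.6), depth_sdlog = 0.3,
                      total_counts = 4000, seed = 1L) {
  cfg <- list(n_matched = as.integer(n_matched),
              n_orthologs = as.integer(n_orthologs),
              n_private = as.integer(n_private),
              cells_per_type = as.integer(cells_per_type),
              markers_per_type = as.integer(markers_per_type),
              marker_lfc = marker_lfc, continuum_share = continuum_share,
              spec_similarity = spec_similarity,
              dispersion = dispersion, frac_one_to_many = frac_one_to_many,
              tie_prob = tie_prob, n_libraries = as.integer(n_libraries),
              library_depth = rep_len(library_depth, n_libraries),
              depth_sdlog = depth_sdlog, total_counts = total_counts,
              seed = as.integer(seed))
  with(cfg, {
    if (n_matched < 2L) stop("n_matched must be >= 2 (continuum needs 2 types)")
    if (any(c(n_orthologs, n_private, cells_per_type, markers_per_type,
              n_libraries) < 1L)) stop("all counts must be positive")
    if (marker_lfc <= 0) stop("marker_lfc must be > 0")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (continuum_share < 0 || continuum_share > 1)
      stop("continuum_share must be in [0, 1]")
    if (spec_similarity < 0 || spec_similarity > 1)
      stop("spec_similarity must be in [0, 1]")
    if (markers_per_type * (n_matched + 2L) > n_orthologs)
      stop("more marker genes requested than ortholog genes available")
    if (markers_per_type > n_private)
      stop("species-specific markers exceed private genes")
  })
  structure(cfg, class = "SimConfig")
}

.sim_type_names <- function(cfg, species) {
  matched <- c("prog", "diff",
               if (cfg$n_matched > 2L) paste0("t", seq_len(cfg$n_matched - 2L)))
  c(paste0(matched, "_", species), paste0("spec_", species))
}

# per-type mean programs on [orthologs, private] genes of one species;
# the species-specific type marks its own ortholog genes (species-specific
# usage of conserved genes, different genes in each species) plus private genes
.sim_programs <- function(cfg, base_orth, base_priv, marker_idx,
                          spec_orth, spec_priv_idx) {
  G <- cfg$n_orthologs; P <- cfg$n_private
  types <- length(marker_idx) + 1L
  M <- matrix(rep(c(base_orth, base_priv), types), G + P, types)
  for (k in seq_along(marker_idx))
    M[marker_idx[[k]]$idx, k] <- M[marker_idx[[k]]$idx, k] *
      exp(marker_idx[[k]]$lfc)
  M[spec_orth$idx, types] <- M[spec_orth$idx, types] * exp(spec_orth$lfc)
  M[G + spec_priv_idx, types] <- M[G + spec_priv_idx, types] *
    exp(cfg$marker_lfc)
  M
}

.sim_counts <- function(cfg, programs, genes, species) {
  n_types <- ncol(programs)
  n <- cfg$cells_per_type * n_types
  type_of <- rep(seq_len(n_types), each = cfg$cells_per_type)
  lib_of <- rep_len(seq_len(cfg$n_libraries), n)
  depth <- cfg$library_depth[lib_of] *
    stats::rlnorm(n, -cfg$depth_sdlog^2 / 2, cfg$depth_sdlog)
  prop <- sweep(programs, 2, colSums(programs), `/`)
  mu <- prop[, type_of, drop = FALSE] *
    rep(depth * cfg$total_counts, each = nrow(prop))
  counts <- if (cfg$dispersion > 0)
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
  else stats::rpois(length(mu), mu)
  counts <- matrix(counts, nrow(prop), n,
                   dimnames = list(genes,
                                   sprintf("%s_c%05d", species, seq_len(n))))
  attr(counts, "scale") <- "raw_counts"
  list(counts = counts, type_idx = type_of, library = paste0("lib", lib_of))
}

#' Simulate a two-species dataset pair with planted homology
#'
#' Generates negative-binomial single-cell counts for two species whose
#' matched cell types share latent expression programs through a true
#' one-to-one ortholog map, plus a noisy many-to-many ortholog candidate
#' table (true pairs carry the highest weighted scores and the
#' best-score-reverse flag; decoys carry lower or tied scores) and the
#' ground truth needed to score recovery.
#'
#' @param config A [simConfig()] object.
#' @return A list with \code{counts_a}, \code{labels_a}, \code{library_a}
#'   (and the \code{_b} counterparts), \code{candidates} (the ortholog
#'   candidate table), \code{truth} (planted type pairs, per-type marker
#'   lists, true ortholog map), and \code{config}.
#' @export
simulatePair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    G <- cfg$n_orthologs; P <- cfg$n_private
    genes_a <- c(sprintf("ga%05d", seq_len(G)), sprintf("pa%05d", seq_len(P)))
    genes_b <- c(sprintf("gb%05d", seq_len(G)), sprintf("pb%05d", seq_len(P)))

    base_orth <- stats::rlnorm(G, 0, 1)
    base_priv_a <- stats::rlnorm(P, 0, 1)
    base_priv_b <- stats::rlnorm(P, 0, 1)

    # disjoint marker blocks on ortholog genes, shared by both species
    n_marked <- cfg$markers_per_type * cfg$n_matched
    marked <- sample.int(G, n_marked)
    blocks <- split(marked, rep(seq_len(cfg$n_matched),
                                each = cfg$markers_per_type))
    marker_idx <- lapply(blocks, function(ii)
      list(idx = ii, lfc = rep(cfg$marker_lfc, length(ii))))
    # progenitor -> differentiated continuum: type 2 re-uses part of type 1
    n_shared <- round(cfg$continuum_share * cfg$markers_per_type)
    if (n_shared > 0) {
      shared <- blocks[[1L]][seq_len(n_shared)]
      marker_idx[[2L]]$idx <- c(marker_idx[[2L]]$idx, shared)
      marker_idx[[2L]]$lfc <- c(marker_idx[[2L]]$lfc,
                                rep(cfg$marker_lfc / 2, n_shared))
    }
    free <- setdiff(seq_len(G), marked)
    so <- sample(free, 2L * cfg$markers_per_type)
    # each species-specific type is a derived specialist: it co-expresses,
    # at half effect, parts of two matched identities' programs — different
    # identity combinations and disjoint gene subsets in the two species —
    # so it has conserved-lineage background without a homologous partner
    half <- round(cfg$spec_similarity * cfg$markers_per_type) %/% 2L
    nm <- cfg$n_matched
    ids_a <- c(min(3L, nm), min(4L, nm))
    ids_b <- c(min(5L, nm), min(3L, nm))
    lean_a <- c(blocks[[ids_a[1]]][seq_len(half)],
                blocks[[ids_a[2]]][seq_len(half)])
    lean_b <- c(blocks[[ids_b[1]]][half + seq_len(half)],
                blocks[[ids_b[2]]][half + seq_len(half)])
    spec_orth_a <- list(idx = c(so[seq_len(cfg$markers_per_type)], lean_a),
                        lfc = c(rep(cfg$marker_lfc, cfg$markers_per_type),
                                rep(cfg$marker_lfc / 2, length(lean_a))))
    spec_orth_b <- list(idx = c(so[-seq_len(cfg$markers_per_type)], lean_b),
                        lfc = c(rep(cfg$marker_lfc, cfg$markers_per_type),
                                rep(cfg$marker_lfc / 2, length(lean_b))))
    spec_priv_a <- sample.int(P, cfg$markers_per_type)
    spec_priv_b <- sample.int(P, cfg$markers_per_type)

    prog_a <- .sim_programs(cfg, base_orth, base_priv_a, marker_idx,
                            spec_orth_a, spec_priv_a)
    prog_b <- .sim_programs(cfg, base_orth, base_priv_b, marker_idx,
                            spec_orth_b, spec_priv_b)

    types_a <- .sim_type_names(cfg, "A")
    types_b <- .sim_type_names(cfg, "B")
    sim_a <- .sim_counts(cfg, prog_a, genes_a, "A")
    sim_b <- .sim_counts(cfg, prog_b, genes_b, "B")
    labels_a <- stats::setNames(types_a[sim_a$type_idx], colnames(sim_a$counts))
    labels_b <- stats::setNames(types_b[sim_b$type_idx], colnames(sim_b$counts))

    # candidate table: true pairs + decoys on a fraction of genes
    true_score <- stats::runif(G, 10, 15)
    cand <- data.frame(gene_a = genes_a[seq_len(G)],
                       gene_b = genes_b[seq_len(G)],
                       weighted_score = true_score,
                       best_score_reverse = TRUE,
                       stringsAsFactors = FALSE)
    n_decoy_src <- round(cfg$frac_one_to_many * G)
    if (n_decoy_src > 0) {
      src <- sample.int(G, n_decoy_src)
      dec <- lapply(src, function(i) {
        k <- sample(1:2, 1)
        tgt <- sample(setdiff(seq_len(G), i), k)
        tie <- stats::runif(k) < cfg$tie_prob
        data.frame(gene_a = genes_a[i], gene_b = genes_b[tgt],
                   weighted_score = ifelse(tie, true_score[i],
                                           stats::runif(k, 1, 9)),
                   best_score_reverse = FALSE, stringsAsFactors = FALSE)
      })
      cand <- rbind(cand, do.call(rbind, dec))
      cand <- cand[!duplicated(cand[, c("gene_a", "gene_b")]), , drop = FALSE]
    }
    rownames(cand) <- NULL

    matched_pairs <- data.frame(
      type_a = types_a[seq_len(cfg$n_matched)],
      type_b = types_b[seq_len(cfg$n_matched)], stringsAsFactors = FALSE)
    markers_a <- lapply(marker_idx, function(m) genes_a[m$idx])
    names(markers_a) <- types_a[seq_len(cfg$n_matched)]
    markers_a[["spec_A"]] <- genes_a[c(spec_orth_a$idx, G + spec_priv_a)]

    list(counts_a = sim_a$counts, labels_a = labels_a,
         library_a = sim_a$library,
         counts_b = sim_b$counts, labels_b = labels_b,
         library_b = sim_b$library,
         candidates = cand,
         truth = list(pairs = matched_pairs, markers_a = markers_a,
                      ortholog_map = data.frame(gene_a = genes_a[seq_len(G)],
                                                gene_b = genes_b[seq_len(G)],
                                                stringsAsFactors = FALSE)),
         config = cfg)
  })
}

#' Precision and recall of a conservation map against planted truth
#'
#' Compares the retained pairs of a conservation map with the planted
#' homologous type pairs of a simulation.
#'
#' @param map A \linkS4class{ConservationMap}.
#' @param truth The \code{truth} element of a [simulatePair()] result (or
#'   any list with a \code{pairs} data.frame of \code{type_a},
#'   \code{type_b}).
#' @return List with \code{precision}, \code{recall}, \code{tp},
#'   \code{n_retained}, \code{n_planted}, and \code{empty_retained}
#'   (\code{TRUE} when nothing was retained, in which case precision is
#'   reported as 0).
#' @export
truthMetrics <- function(map, truth) {
  stopifnot(is(map, "ConservationMap"))
  ret <- retainedPairs(map)
  key <- function(a, b) paste(a, b, sep = "\r")
  planted <- key(truth$pairs$type_a, truth$pairs$type_b)
  got <- key(ret$type_a, ret$type_b)
  tp <- length(intersect(got, planted))
  empty <- length(got) == 0L
  list(precision = if (empty) 0 else tp / length(got),
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       tp = tp, n_retained = length(got), n_planted = length(planted),
       empty_retained = empty)
}
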