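# small fixtures built in code

quick_sim <- function(seed = 1, ...) {
  args <- list(n_orthologs = 600L, n_private = 100L, cells_per_type = 60L,
               markers_per_type = 30L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulatePair(do.call(simConfig, args))
}

# random many-to-many candidate table + expression summaries
random_candidates <- function(seed, n_a = 50, n_b = 50, max_cand = 8) {
  withr::with_seed(seed, {
    gene_a <- sprintf("a%02d", seq_len(n_a))
    gene_b <- sprintf("b%02d", seq_len(n_b))
    rows <- do.call(rbind, lapply(gene_a, function(a) {
      k <- sample.int(max_cand, 1)
      data.frame(gene_a = a, gene_b = sample(gene_b, k),
                 weighted_score = sample(1:6, k, replace = TRUE),
                 best_score_reverse = sample(c(TRUE, FALSE), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rows <- rows[!duplicated(rows[, c("gene_a", "gene_b")]), ]
    ea <- data.frame(gene = gene_a,
                     mean_expr = round(runif(n_a, 0, 5), 2),
                     n_detected = sample(0:20, n_a, replace = TRUE),
                     frac_detected = round(runif(n_a), 2))
    eb <- data.frame(gene = gene_b,
                     mean_expr = round(runif(n_b, 0, 5), 2),
                     n_detected = sample(0:20, n_b, replace = TRUE),
                     frac_detected = round(runif(n_b), 2))
    list(cand = rows, ea = ea, eb = eb)
  })
}

expr_summary_of <- function(genes, mean_expr = 1, n_detected = 10,
                            frac_detected = 0.5) {
  data.frame(gene = genes,
             mean_expr = rep_len(mean_expr, length(genes)),
             n_detected = rep_len(as.integer(n_detected), length(genes)),
             frac_detected = rep_len(frac_detected, length(genes)))
}

# small labeled lognorm matrix with clean type structure
toy_lognorm <- function(n_types = 3, cells_per_type = 20, n_genes = 40,
                        markers = 5, lfc = 2, seed = 1) {
  withr::with_seed(seed, {
    types <- paste0("T", seq_len(n_types))
    labels <- rep(types, each = cells_per_type)
    base <- matrix(rlnorm(n_genes * length(labels), 0, 0.3),
                   n_genes, length(labels))
    for (k in seq_len(n_types)) {
      rows <- ((k - 1) * markers + 1):(k * markers)
      base[rows, labels == types[k]] <-
        base[rows, labels == types[k]] * exp(lfc)
    }
    m <- log1p(base)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("c%03d", seq_along(labels)))
    attr(m, "scale") <- "lognorm"
    list(mat = m, labels = stats::setNames(labels, colnames(m)),
         marker_rows = lapply(seq_len(n_types), function(k)
           sprintf("g%03d", ((k - 1) * markers + 1):(k * markers))))
  })
}

make_profiles <- function(mat, types, dataset = "D") {
  labels <- stats::setNames(types, colnames(mat))
  pseudoBulk(mat, labels, dataset = dataset)
}

with_scale <- function(m, scale = "lognorm") {
  attr(m, "scale") <- scale
  m
}

# profile container with columns exactly as given (no type sorting)
raw_profiles <- function(m, dataset = "B") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(profiles = m),
    colData = S4Vectors::DataFrame(cell_type = colnames(m),
                                   dataset = dataset, n_cells = 1L,
                                   row.names = colnames(m)))
  new("PseudoProfiles", se, kind = "pseudo_bulk")
}
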