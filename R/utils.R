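`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce sparse input to a dense genes x cells matrix with unique ids
.as_expression_matrix <- function(x) {
  if (is(x, "Matrix")) {
    sc <- attr(x, "scale")
    x <- as.matrix(x)
    attr(x, "scale") <- sc
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix")
  if (is.null(rownames(x)))
    stop("expression matrix must have gene ids as rownames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids in expression matrix")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("duplicate cell ids in expression matrix")
  x
}

.delog_values <- function(x) pmax(expm1(x), 0)

# midrank helper (stats::rank with ties.method = "average")
.midrank <- function(x) rank(x, ties.method = "average")

.check_labels <- function(x, labels) {
  if (is.null(colnames(x)))
    stop("expression matrix must have cell ids as colnames")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(x))
      stop("labels must be named by cell id or match ncol(x)")
    names(labels) <- colnames(x)
  }
  missing <- setdiff(colnames(x), names(labels))
  if (length(missing))
    stop("unlabeled cells: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  as.character(labels[colnames(x)])
}
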