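#' Feature table: samples x named features plus the LAI target
#'
#' The regression substrate: a numeric feature matrix with unique column
#' names, a target vector (measured LAI) and sample ids.
#'
#' @param x numeric matrix (N samples x J features) with unique column names.
#' @param y numeric target vector of length N, no missing values.
#' @param ids sample identifiers (default `1:N`).
#' @return list of class `feature_table` with elements `x`, `y`, `ids`.
#' @export
feature_table <- function(x, y, ids = seq_len(nrow(x))) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("feature matrix must have unique column names")
  }
  if (ncol(x) < 1) stop("at least one feature is required")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(y)) stop("target vector must have no missing values")
  structure(list(x = x, y = as.numeric(y), ids = ids), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; LAI in [%.2f, %.2f]\n",
              nrow(x$x), ncol(x$x), min(x$y), max(x$y)))
  invisible(x)
}

# subset a feature table by sample ids
ft_subset <- function(table, ids) {
  keep <- match(ids, table$ids)
  feature_table(table$x[keep, , drop = FALSE], table$y[keep], table$ids[keep])
}
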