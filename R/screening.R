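#' Pearson correlation screening of candidate features
#'
#' Two-sided Pearson test of every feature against the LAI target. A
#' feature is selected when its |r|, rounded to two decimals, reaches the
#' threshold and the test p-value is below `alpha`. Features listed at
#' exactly the threshold after rounding are retained (the screening rule
#' is inclusive). Constant features are excluded with a warning.
#'
#' @param table a [feature_table()], N >= 3.
#' @param threshold selection threshold on |r| after 2-decimal rounding.
#' @param alpha significance level for the two-sided test.
#' @return data frame of class `screen_report`: `feature, r, p, selected`,
#'   with the threshold and alpha stored as attributes.
#' @export
pearson_screen <- function(table, threshold = 0.80, alpha = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  n <- length(table$y)
  if (n < 3) stop("need at least 3 samples to screen")
  # per-feature complete observations; a feature is screenable when it has
  # >= 3 finite values and nonzero spread on them
  stats_j <- apply(table$x, 2, function(v) {
    ok <- is.finite(v)
    nj <- sum(ok)
    if (nj < 3 || stats::sd(v[ok]) == 0 || stats::sd(table$y[ok]) == 0) {
      return(c(r = NA_real_, n = nj))
    }
    c(r = stats::cor(v[ok], table$y[ok]), n = nj)
  })
  const <- !is.finite(stats_j["r", ])
  if (all(const)) stop("all features are constant; nothing to screen")
  if (any(const)) {
    warning("excluding ", sum(const), " constant/degenerate feature(s): ",
            paste(utils::head(colnames(table$x)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
  }
  r <- stats_j["r", !const]
  nj <- stats_j["n", !const]
  # two-sided t test of rho = 0 on n - 2 df
  tstat <- r * sqrt((nj - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = nj - 2)
  out <- data.frame(
    feature = colnames(table$x)[!const], r = unname(r), p = unname(p),
    selected = unname(round(abs(r), 2) >= threshold & p < alpha),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_report", "data.frame")
  out
}

#' Selected feature names from a screen report
#'
#' @param report a `screen_report`.
#' @param top_if_empty if no feature passes, fall back to the single best
#'   feature by |r| (with a warning) instead of returning an empty set.
#' @return character vector of selected feature names, ordered by
#'   decreasing |r|.
#' @export
selected_features <- function(report, top_if_empty = FALSE) {
  sel <- report[report$selected, , drop = FALSE]
  if (!nrow(sel) && top_if_empty && nrow(report)) {
    warning("no feature passed screening; falling back to the best single feature")
    sel <- report[which.max(abs(report$r)), , drop = FALSE]
  }
  sel$feature[order(-abs(sel$r))]
}
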