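#' SPXY calibration/validation partitioning
#'
#' Sample set partitioning based on joint x-y distance: pairwise Euclidean
#' distances are computed in feature space, `d_x(p,q) = sqrt(sum_j
#' (x_p(j) - x_q(j))^2)`, and in target space, `d_y(p,q) = |y_p - y_q|`,
#' each normalized by its maximum and summed, `d_xy = d_x/max d_x +
#' d_y/max d_y`. Selection follows the Kennard-Stone rule on `d_xy`: the
#' calibration set is seeded with the most mutually distant pair, then the
#' sample whose minimum distance to the current calibration set is largest
#' is added until `round(cal_fraction * N)` samples are selected; the rest
#' form the validation set. Ties are broken by the lowest sample index, so
#' the split is fully deterministic.
#'
#' Features are z-score standardized before `d_x` by default, since the
#' table mixes unitless indices with plant height in cm; pass
#' `standardize = FALSE` for raw distances.
#'
#' @param table a [feature_table()] with N >= 4 (N >= 3 accepted when the
#'   requested calibration size is 2).
#' @param cal_fraction fraction of samples assigned to calibration (0, 1).
#' @param standardize z-score features before computing `d_x`.
#' @return list of class `spxy_split` with `calibration` and `validation`
#'   id vectors (disjoint, exhaustive).
#' @export
spxy_split <- function(table, cal_fraction = 0.7, standardize = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  n <- length(table$y)
  if (n < 3) stop("need at least 3 samples to split")
  if (cal_fraction <= 0 || cal_fraction >= 1) stop("cal_fraction must be in (0, 1)")
  x <- table$x
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    keep <- is.finite(sds) & sds > 0
    x <- scale(x[, keep, drop = FALSE])
    if (!ncol(x)) x <- matrix(0, n, 1)
  }
  dx <- as.matrix(stats::dist(x))
  dy <- abs(outer(table$y, table$y, `-`))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0) stop("degenerate table: all samples identical")
  dxy <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)

  n_cal <- round(cal_fraction * n)
  n_cal <- max(2L, min(as.integer(n_cal), n - 1L))
  # seed: pair with maximal joint distance, earliest indices on ties
  best <- which(dxy == max(dxy), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  sel <- sort(best[1, ])
  while (length(sel) < n_cal) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- apply(dxy[remaining, sel, drop = FALSE], 1, min)
    sel <- c(sel, remaining[which.max(mind)])  # which.max -> lowest index tie-break
  }
  structure(list(
    calibration = table$ids[sort(sel)],
    validation = table$ids[setdiff(seq_len(n), sel)]
  ), class = "spxy_split")
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d calibration / %d validation samples\n",
              length(x$calibration), length(x$validation)))
  invisible(x)
}
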