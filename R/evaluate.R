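#' Regression accuracy: R2, RMSE and RPD
#'
#' R2 is the squared Pearson correlation between measured and predicted
#' values; RMSE is the residual root mean square error
#' `sqrt(mean((predicted - measured)^2))`; RPD is the ratio of performance
#' to deviation, the population standard deviation of the measured values
#' divided by RMSE (RPD < 1.4 unreliable, 1.4-2.0 moderate, > 2.0 highly
#' reliable). Perfect predictions give RMSE 0 and RPD `Inf`. Zero-variance
#' predictions give R2 = 0 with a warning.
#'
#' @param measured numeric vector of ground-truth values.
#' @param predicted numeric vector of model predictions, same length >= 2.
#' @param label set label, e.g. `"calibration"` or `"validation"`.
#' @return one-row data frame of class `eval_report`:
#'   `label, n, R2, RMSE, RPD`.
#' @export
evaluate <- function(measured, predicted, label = "validation") {
  stopifnot(length(measured) == length(predicted), length(measured) >= 2)
  sdm <- sd_pop(measured)
  if (sdm == 0) stop("measured values have zero variance")
  if (sd_pop(predicted) == 0) {
    warning("predictions have zero variance; R2 reported as 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(measured, predicted)^2
  }
  rmse <- sqrt(mean((predicted - measured)^2))
  rpd <- if (rmse == 0) Inf else sdm / rmse
  structure(
    data.frame(label = label, n = length(measured), R2 = r2,
               RMSE = rmse, RPD = rpd, stringsAsFactors = FALSE),
    class = c("eval_report", "data.frame")
  )
}

#' Classification accuracy of a wheat mask
#'
#' Overall accuracy and Cohen's kappa of a predicted boolean mask against
#' reference labels, from the 2x2 confusion matrix: OA = (TP + TN)/total,
#' kappa = (p_o - p_e)/(1 - p_e) with p_e the chance agreement. If the
#' truth contains a single class, kappa is undefined and reported as NA.
#'
#' @param predicted,truth `wl_raster` masks (nonzero = wheat) or logical
#'   matrices on the same grid.
#' @return list of class `mask_report`: `oa`, `kappa`, `confusion` (2x2,
#'   rows = truth, cols = predicted).
#' @export
evaluate_mask <- function(predicted, truth) {
  pv <- if (inherits(predicted, "wl_raster")) predicted$values else predicted
  tv <- if (inherits(truth, "wl_raster")) truth$values else truth
  if (!identical(dim(pv), dim(tv))) stop("mask grids do not match")
  p <- as.vector(pv) > 0
  t <- as.vector(tv) > 0
  ok <- !is.na(p) & !is.na(t)
  p <- p[ok]; t <- t[ok]
  cm <- matrix(c(sum(!t & !p), sum(!t & p), sum(t & !p), sum(t & p)),
               2, 2, byrow = TRUE,
               dimnames = list(truth = c("soil", "wheat"),
                               predicted = c("soil", "wheat")))
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (length(unique(t)) < 2 || pe == 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(oa = po, kappa = kappa, confusion = cm), class = "mask_report")
}

#' @export
print.mask_report <- function(x, ...) {
  cat(sprintf("<mask_report> OA = %.4f, kappa = %s\n", x$oa,
              ifelse(is.na(x$kappa), "NA", sprintf("%.4f", x$kappa))))
  print(x$confusion)
  invisible(x)
}
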