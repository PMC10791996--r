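#' Train a random forest wheat-pixel classifier
#'
#' Classifies wheat vs soil pixels from eight features: the four
#' reflectance bands plus NDVI, EVI2, REOSAVI and OSAVI, using a random
#' forest with library-default hyperparameters. A random subsample of
#' pixels is used for training to keep fitting fast on large scenes.
#'
#' @param bands named list of `wl_raster` bands `G, R, RE, NIR`.
#' @param labels `wl_raster` (nonzero = wheat) or logical matrix of
#'   reference labels; must contain both classes.
#' @param seed integer RNG seed.
#' @param n_train maximum number of training pixels (sampled without
#'   replacement, stratified by class).
#' @return object of class `wheat_mask_model`.
#' @export
train_wheat_mask <- function(bands, labels, seed = 42L, n_train = 4000L) {
  check_band_set(bands)
  lv <- if (inherits(labels, "wl_raster")) labels$values else labels
  y <- factor(ifelse(as.vector(lv) > 0, "wheat", "soil"),
              levels = c("soil", "wheat"))
  if (length(unique(stats::na.omit(y))) < 2) {
    stop("labels must contain both wheat and soil pixels")
  }
  X <- mask_features(bands)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_along(y), y), function(i) {
      if (length(i) > n_train / 2) sample(i, n_train / 2) else i
    }), use.names = FALSE)
    fit <- randomForest::randomForest(X[idx, , drop = FALSE], y[idx])
    structure(list(fit = fit, seed = seed), class = "wheat_mask_model")
  })
}

mask_features <- function(bands) {
  G <- as.vector(bands$G$values); R <- as.vector(bands$R$values)
  RE <- as.vector(bands$RE$values); NIR <- as.vector(bands$NIR$values)
  cbind(
    G = G, R = R, RE = RE, NIR = NIR,
    NDVI = vi_values("NDVI", G, R, RE, NIR),
    EVI2 = vi_values("EVI2", G, R, RE, NIR),
    REOSAVI = vi_values("REOSAVI", G, R, RE, NIR),
    OSAVI = vi_values("OSAVI", G, R, RE, NIR)
  )
}

#' Predict a wheat mask raster
#'
#' @param model a `wheat_mask_model` from [train_wheat_mask()].
#' @param bands named list of `wl_raster` bands `G, R, RE, NIR`.
#' @return a `wl_raster` with 1 = wheat, 0 = soil, NA where features are
#'   missing.
#' @export
predict_wheat_mask <- function(model, bands) {
  check_band_set(bands)
  X <- mask_features(bands)
  out <- rep(NA_real_, nrow(X))
  ok <- stats::complete.cases(X)
  out[ok] <- as.numeric(stats::predict(model$fit, X[ok, , drop = FALSE]) == "wheat")
  raster_like(bands$G, matrix(out, nrow(bands$G$values), ncol(bands$G$values)))
}
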