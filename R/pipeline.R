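#' Experiment configuration
#'
#' Bundles every stage setting of the end-to-end LAI experiment: scene
#' simulation (or paths to on-disk inputs), GLCM settings, correlation
#' screening, SPXY partitioning, the feature combinations and algorithms
#' to run, and the seed.
#'
#' @param scene a [scene_config()], or a directory written by
#'   [write_scene()] to load instead of simulating.
#' @param glcm a [glcm_config()].
#' @param screen_threshold,screen_alpha Pearson screening threshold on |r|
#'   and significance level.
#' @param cal_fraction calibration fraction for [spxy_split()].
#' @param combinations subset of `"VI", "VITI", "VIPH", "VITIPH"`.
#' @param algorithms subset of `"RF", "XGBOOST", "SVM", "BPNN", "CNN1D",
#'   "LSTM"`.
#' @param seed integer master seed (scene seed and model seeds derive from
#'   it).
#' @param n_points number of ground samples (overrides the scene config).
#' @param output_dir optional directory for stage artifacts (CSV tables);
#'   `NULL` writes nothing.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scene = scene_config(),
                              glcm = glcm_config(),
                              screen_threshold = 0.80, screen_alpha = 0.01,
                              cal_fraction = 0.7,
                              combinations = c("VI", "VITI", "VIPH", "VITIPH"),
                              algorithms = c("RF", "XGBOOST", "SVM",
                                             "BPNN", "CNN1D", "LSTM"),
                              seed = 42L, n_points = NULL,
                              output_dir = NULL) {
  combinations <- match.arg(combinations,
                            c("VI", "VITI", "VIPH", "VITIPH"), several.ok = TRUE)
  algorithms <- match.arg(toupper(algorithms),
                          c("RF", "XGBOOST", "SVM", "BPNN", "CNN1D", "LSTM"),
                          several.ok = TRUE)
  if (!length(combinations) || !length(algorithms)) {
    stop("at least one combination and one algorithm are required")
  }
  if (is.character(scene) && !dir.exists(scene)) {
    stop("scene directory does not exist: ", scene)
  }
  structure(list(
    scene = scene, glcm = glcm,
    screen_threshold = screen_threshold, screen_alpha = screen_alpha,
    cal_fraction = cal_fraction, combinations = combinations,
    algorithms = algorithms, seed = as.integer(seed),
    n_points = n_points, output_dir = output_dir
  ), class = "experiment_config")
}

load_scene_dir <- function(dir) {
  bands <- lapply(c("G", "R", "RE", "NIR"), function(b) {
    read_ascii_grid(file.path(dir, paste0("band_", b, ".asc")))
  })
  names(bands) <- c("G", "R", "RE", "NIR")
  structure(list(
    bands = bands,
    truth_lai = read_ascii_grid(file.path(dir, "truth_lai.asc")),
    truth_ph_cm = read_ascii_grid(file.path(dir, "truth_ph_cm.asc")),
    truth_mask = read_ascii_grid(file.path(dir, "truth_mask.asc")),
    dsm0 = read_ascii_grid(file.path(dir, "dsm0.asc")),
    dsm1 = read_ascii_grid(file.path(dir, "dsm1.asc")),
    points = read_points_csv(file.path(dir, "points.csv")),
    config = NULL
  ), class = "scene_bundle")
}

#' Assemble the per-point feature table of a scene
#'
#' Extracts band reflectance at each sample point (single pixel, matching
#' the 10 x 10 cm field spectral footprint), evaluates the 17 vegetation
#' indices on those values, extracts the 32 GLCM texture layers (single
#' pixel) and expands them into the 1984 texture indices, and extracts
#' DSM-derived plant height as the mean within 0.5 m. The measured LAI of
#' the points is the target.
#'
#' @param bundle a `scene_bundle`.
#' @param glcm a [glcm_config()].
#' @param points sample points (default `bundle$points`).
#' @param stack optional precomputed [texture_stack()] to reuse.
#' @return a [feature_table()] with attribute `groups`, a list naming the
#'   `vi`, `ti` and `ph` feature columns.
#' @export
build_feature_table <- function(bundle, glcm = glcm_config(),
                                points = bundle$points, stack = NULL) {
  bands_pt <- vapply(bundle$bands, extract_at_points, numeric(nrow(points)),
                     points = points, radius = 0)
  vi <- vapply(vi_names(), function(nm) {
    vi_values(nm, bands_pt[, "G"], bands_pt[, "R"],
              bands_pt[, "RE"], bands_pt[, "NIR"])
  }, numeric(nrow(points)))

  if (is.null(stack)) stack <- texture_stack(bundle$bands, glcm)
  tex <- vapply(stack, extract_at_points, numeric(nrow(points)),
                points = points, radius = 0)
  colnames(tex) <- names(stack)
  defs <- enumerate_texture_indices(names(stack))
  ti <- texture_index_values(defs, tex)

  ph_raster <- compute_ph(bundle$dsm0, bundle$dsm1)
  ph <- ph_at_points(ph_raster, points, radius = 0.5)

  x <- cbind(vi, ti, PH = ph)
  tab <- feature_table(x, points$lai, ids = points$id)
  attr(tab, "groups") <- list(vi = colnames(vi), ti = colnames(ti), ph = "PH")
  attr(tab, "ti_defs") <- defs
  tab
}

combination_features <- function(combo, vi_sel, ti_sel) {
  switch(combo,
    VI = vi_sel,
    VITI = c(vi_sel, ti_sel),
    VIPH = c(vi_sel, "PH"),
    VITIPH = c(vi_sel, ti_sel, "PH")
  )
}

#' Run the end-to-end LAI estimation experiment
#'
#' Simulates (or loads) the scene, builds the feature table, screens VI and
#' TI candidates by Pearson correlation, then for every requested feature
#' combination partitions the samples with SPXY on that combination's
#' features and fits and evaluates every requested algorithm on the
#' calibration/validation sets.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_result` with elements `results`
#'   (data frame: combination, algorithm, set, n, R2, RMSE, RPD), `bundle`,
#'   `table`, `screen` (list of VI/TI screen reports), `selected` (feature
#'   names per combination), `splits`, `models` (fitted `lai_model`s,
#'   keyed `combination.algorithm`), and `stack`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  bundle <- stage("simulate", {
    if (is.character(config$scene)) load_scene_dir(config$scene)
    else {
      sc <- config$scene
      sc$seed <- config$seed
      if (!is.null(config$n_points)) sc$n_points <- as.integer(config$n_points)
      generate_scene(sc)
    }
  })

  stack <- stage("texture", texture_stack(bundle$bands, config$glcm))
  tab <- stage("features", build_feature_table(bundle, config$glcm, stack = stack))
  groups <- attr(tab, "groups")

  # candidate features must be defined at every sample to enter a model
  finite_cols <- function(cols) {
    cols[colSums(!is.finite(tab$x[, cols, drop = FALSE])) == 0]
  }
  screen <- stage("screen", {
    list(
      vi = pearson_screen(
        feature_table(tab$x[, finite_cols(groups$vi), drop = FALSE],
                      tab$y, tab$ids),
        config$screen_threshold, config$screen_alpha),
      ti = pearson_screen(
        feature_table(tab$x[, finite_cols(groups$ti), drop = FALSE],
                      tab$y, tab$ids),
        config$screen_threshold, config$screen_alpha)
    )
  })
  vi_sel <- selected_features(screen$vi, top_if_empty = TRUE)
  ti_sel <- selected_features(screen$ti, top_if_empty = TRUE)

  results <- list(); models <- list(); splits <- list(); selected <- list()
  for (combo in config$combinations) {
    feats <- combination_features(combo, vi_sel, ti_sel)
    selected[[combo]] <- feats
    sub <- feature_table(tab$x[, feats, drop = FALSE], tab$y, tab$ids)
    split <- stage("split", spxy_split(sub, config$cal_fraction))
    splits[[combo]] <- split
    cal <- ft_subset(sub, split$calibration)
    val <- ft_subset(sub, split$validation)
    for (alg in config$algorithms) {
      key <- paste(combo, alg, sep = ".")
      fit <- stage(paste0("train[", key, "]"),
                   fit_model(model_spec(alg, seed = config$seed), cal$x, cal$y))
      models[[key]] <- fit
      for (set in c("calibration", "validation")) {
        d <- if (set == "calibration") cal else val
        ev <- stage(paste0("evaluate[", key, "]"),
                    evaluate(d$y, predict(fit, d$x), set))
        results[[length(results) + 1L]] <- cbind(
          data.frame(combination = combo, algorithm = alg), ev)
      }
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(screen$vi),
                     file.path(config$output_dir, "screen_vi.csv"),
                     row.names = FALSE)
    sel_ti <- screen$ti[screen$ti$selected, , drop = FALSE]
    utils::write.csv(as.data.frame(sel_ti),
                     file.path(config$output_dir, "screen_ti_selected.csv"),
                     row.names = FALSE)
    write_points_csv(bundle$points, file.path(config$output_dir, "points.csv"))
  }

  structure(list(results = results, bundle = bundle, table = tab,
                 screen = screen, selected = selected, splits = splits,
                 models = models, stack = stack, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$results, digits = 3)
  invisible(x)
}

#' Per-pixel LAI inversion map
#'
#' Assembles the fitted model's feature rasters (vegetation indices,
#' texture indices from the stack, plant height), applies the model on
#' wheat-mask pixels and returns the LAI map; non-wheat pixels are nodata.
#'
#' @param fit a `lai_model` from [fit_model()].
#' @param bundle a `scene_bundle` providing bands and DSMs.
#' @param stack a [texture_stack()] of the same scene.
#' @param mask `wl_raster` wheat mask (nonzero = wheat), or `NULL` to map
#'   every valid pixel.
#' @param ti_defs texture-index definitions (default: the full enumeration
#'   of the stack's layers).
#' @return a `wl_raster` of predicted LAI.
#' @export
make_lai_map <- function(fit, bundle, stack, mask = bundle$truth_mask,
                         ti_defs = enumerate_texture_indices(stack)) {
  template <- bundle$bands$G
  nr <- nrow(template$values); nc <- ncol(template$values)
  n_pix <- nr * nc
  feat_raster <- function(name) {
    if (name == "PH") return(compute_ph(bundle$dsm0, bundle$dsm1)$values)
    if (name %in% vi_names() || name == "OSAVI") {
      return(compute_vi(bundle$bands, name)$values)
    }
    if (!is.null(stack[[name]])) return(stack[[name]]$values)
    hit <- which(ti_defs$name == name)
    if (length(hit)) {
      return(compute_texture_index(ti_defs[hit[1], ], stack)$values)
    }
    stop("cannot compute feature raster '", name, "'")
  }
  X <- matrix(NA_real_, n_pix, length(fit$features),
              dimnames = list(NULL, fit$features))
  for (f in fit$features) X[, f] <- as.vector(feat_raster(f))
  keep <- stats::complete.cases(X)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "wl_raster")) mask$values else mask
    keep <- keep & !is.na(as.vector(mv)) & as.vector(mv) > 0
  }
  out <- rep(NA_real_, n_pix)
  if (any(keep)) out[keep] <- predict(fit, X[keep, , drop = FALSE])
  raster_like(template, matrix(out, nr, nc))
}

#' Render an LAI map to PNG
#'
#' @param map a `wl_raster` of LAI.
#' @param path output PNG path.
#' @param zlim color scale limits (default data range).
#' @return `path`, invisibly.
#' @export
render_lai_map <- function(map, path, zlim = NULL) {
  v <- map$values
  if (is.null(zlim)) zlim <- range(v, na.rm = TRUE)
  ctr <- cell_centers(map)
  grDevices::png(path, width = 900, height = 800)
  on.exit(grDevices::dev.off())
  # image() wants x ascending and a transposed, south-up matrix
  graphics::image(ctr$x, rev(ctr$y), t(v[nrow(v):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  zlim = zlim, xlab = "Easting (m)", ylab = "Northing (m)",
                  main = "Predicted LAI (m²/m²)", useRaster = TRUE,
                  asp = 1)
  invisible(path)
}
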