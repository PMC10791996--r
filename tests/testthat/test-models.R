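make_xy <- function(n = 40, j = 3, seed = 2, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * j), n, j, dimnames = list(NULL, paste0("f", seq_len(j))))
  y <- 2 * X[, 1] + noise * rnorm(n)
  list(X = X, y = y)
}

test_that("a constant target is predicted as that constant", {
  d <- make_xy(30, 3)
  y_const <- rep(3.2, 30)
  for (alg in c("RF", "XGBOOST", "SVM", "BPNN", "CNN1D", "LSTM")) {
    m <- fit_model(model_spec(alg, seed = 1), d$X, y_const)
    expect_lt(max(abs(predict(m, d$X) - 3.2)), 1e-6, label = alg)
  }
})

test_that("a tuned SVM learns an exact linear relation", {
  d <- make_xy(50, 1, seed = 4, noise = 0)
  m <- fit_model(model_spec("SVM", seed = 1), d$X, d$y)
  r2 <- evaluate(d$y, predict(m, d$X), "calibration")$R2
  expect_gte(r2, 0.99)
})

test_that("RF, XGBoost and SVM fits are deterministic for a fixed seed", {
  d <- make_xy(40, 4, seed = 6)
  for (alg in c("RF", "XGBOOST", "SVM")) {
    m1 <- fit_model(model_spec(alg, seed = 7), d$X, d$y)
    m2 <- fit_model(model_spec(alg, seed = 7), d$X, d$y)
    expect_identical(predict(m1, d$X), predict(m2, d$X), label = alg)
  }
})

test_that("defaults carry the study hyperparameters", {
  hp <- wheatlai:::default_hp("RF")
  expect_equal(hp$ntree, 500)
  expect_equal(hp$nodesize, 8)
  hp <- wheatlai:::default_hp("XGBOOST")
  expect_equal(hp[c("eta", "max_depth", "gamma", "alpha", "lambda",
                    "subsample", "colsample_bytree")],
               list(eta = 0.5, max_depth = 1, gamma = 0.01, alpha = 0.02,
                    lambda = 0.1, subsample = 0.3, colsample_bytree = 0.5))
  expect_equal(wheatlai:::default_hp("BPNN")$size, 1)
  expect_equal(range(log2(wheatlai:::default_hp("SVM")$cost_grid)), c(-8, 8))
})

test_that("invalid training data is rejected with an informative message", {
  d <- make_xy(20, 2)
  X_bad <- d$X; X_bad[3, 2] <- NaN
  expect_error(fit_model(model_spec("RF"), X_bad, d$y), "f2")
  expect_error(fit_model(model_spec("RF"), d$X[1:3, ], d$y[1:3]), "at least 5")
  m <- fit_model(model_spec("RF", seed = 1), d$X, d$y)
  expect_error(predict(m, d$X[, 1, drop = FALSE]), "missing feature")
})

test_that("all six algorithms beat the mean predictor on signal data", {
  d <- make_xy(60, 3, seed = 10, noise = 0.3)
  for (alg in c("RF", "XGBOOST", "SVM", "BPNN", "CNN1D", "LSTM")) {
    m <- fit_model(model_spec(alg, seed = 3), d$X, d$y)
    r2 <- evaluate(d$y, predict(m, d$X), "calibration")$R2
    expect_gt(r2, 0.5, label = alg)
  }
})

test_that("calibration fit is at least as good as validation for tree ensembles", {
  b <- small_scene(seed = 23, width = 128, height = 128, n_points = 100)
  tab <- build_feature_table(b)
  groups <- attr(tab, "groups")
  keep <- c(groups$vi[1:5], "PH")
  sub <- feature_table(tab$x[, keep], tab$y, tab$ids)
  wins <- 0
  for (s in 1:5) {
    sp <- spxy_split(sub)
    cal <- wheatlai:::ft_subset(sub, sp$calibration)
    val <- wheatlai:::ft_subset(sub, sp$validation)
    m <- fit_model(model_spec("XGBOOST", seed = s), cal$x, cal$y)
    r2c <- evaluate(cal$y, predict(m, cal$x), "calibration")$R2
    r2v <- evaluate(val$y, predict(m, val$x), "validation")$R2
    wins <- wins + (r2c >= r2v)
  }
  expect_gte(wins, 4)
})
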