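test_that("select_features ranks by univariate F-statistic (lm oracle)", {
  set.seed(21)
  n <- 40
  y <- rnorm(n)
  X <- cbind(y + rnorm(n, 0, 0.01),   # near-perfect
             rnorm(n), rnorm(n))      # noise
  expect_equal(select_features(X, y, 1), 1L)

  # 3-feature toy: ranking must match per-feature lm F-statistics
  X2 <- cbind(f1 = y + rnorm(n, 0, 2), f2 = y + rnorm(n, 0, 0.5),
              f3 = rnorm(n))
  f_lm <- apply(X2, 2, function(x) summary(lm(y ~ x))$fstatistic[["value"]])
  expect_equal(select_features(X2, y, 3), order(-f_lm))
  expect_equal(select_features(X2, y, 2), order(-f_lm)[1:2])

  # k = d returns all features; k out of range errors
  expect_length(select_features(X2, y, 3), 3)
  expect_error(select_features(X2, y, 4), "out of range")
  expect_error(select_features(X2, rep(1, n), 1), "constant response")
  # constant features rank last
  X3 <- cbind(rep(5, n), y)
  expect_equal(select_features(X3, y, 2), c(2L, 1L))
})

test_that("evaluate_predictions matches the R2/MSE definitions", {
  truth <- c(1, 2, 3)
  expect_equal(evaluate_predictions(truth, truth), list(r2 = 1, mse = 0))
  ev0 <- evaluate_predictions(rep(mean(truth), 3), truth)
  expect_equal(ev0$r2, 0)
  # hand computation: SS_res = 1, SS_tot = 2, mse = 1/3
  ev <- evaluate_predictions(c(1, 2, 4), truth)
  expect_equal(ev$mse, 1 / 3)
  expect_equal(ev$r2, 0.5)
  # zero-variance truth -> NA sentinel
  expect_true(is.na(evaluate_predictions(c(1, 2), c(5, 5))$r2))
})

test_that("knn regressor matches FNN oracle (uniform) and hand-computed weights", {
  skip_if_not_installed("FNN")
  set.seed(31)
  Xtr <- matrix(rnorm(200), 50, 4)
  ytr <- rnorm(50)
  Xte <- matrix(rnorm(40), 10, 4)
  for (k in c(1, 3, 7)) {
    m <- fit_regressor("knn", Xtr, ytr, list(k = k, weights = "uniform"))
    oracle <- FNN::knn.reg(Xtr, Xte, ytr, k = k)$pred
    expect_equal(unname(predict(m, Xte)), oracle, tolerance = 1e-10)
  }
  # distance weights on a hand-checkable configuration
  Xtr2 <- matrix(c(0, 1, 3), ncol = 1)
  ytr2 <- c(10, 20, 40)
  m2 <- fit_regressor("knn", Xtr2, ytr2, list(k = 2, weights = "distance"))
  # query at 2: neighbours x=1 (d=1, y=20) and x=3 (d=1, y=40) -> 30
  expect_equal(unname(predict(m2, matrix(2))), 30)
  # query at 0.5: d = 0.5 and 0.5 to x=0,1 -> mean(10, 20) = 15
  expect_equal(unname(predict(m2, matrix(0.5))), 15)
  # exact match retrieval: zero distance returns that training value
  m3 <- fit_regressor("knn", Xtr, ytr, list(k = 1))
  expect_equal(unname(predict(m3, Xtr[7, , drop = FALSE])), ytr[7])
})

test_that("forest: single unbagged tree recovers group means; seeded determinism", {
  # two well-separated clusters in one feature: a depth-1 tree must
  # predict each cluster's mean
  X <- matrix(c(1, 1.1, 0.9, 5, 5.1, 4.9), ncol = 1)
  y <- c(10, 12, 11, 30, 31, 32)
  m <- fit_regressor("rfr", X, y,
                     list(n_trees = 1L, max_depth = 1L, mtry = 1L,
                          bootstrap = FALSE), seed = 1)
  expect_equal(unname(predict(m, matrix(c(0.5, 6)))), c(11, 31))

  set.seed(41)
  Xr <- matrix(rnorm(300), 60, 5)
  yr <- Xr[, 1] * 2 + rnorm(60, 0, 0.1)
  m1 <- fit_regressor("rfr", Xr, yr, list(n_trees = 50L), seed = 9)
  m2 <- fit_regressor("rfr", Xr, yr, list(n_trees = 50L), seed = 9)
  p1 <- predict(m1, Xr); p2 <- predict(m2, Xr)
  expect_identical(p1, p2)
  expect_false(identical(p1, predict(
    fit_regressor("rfr", Xr, yr, list(n_trees = 50L), seed = 10), Xr)))
  # predictions are averages of training targets: bounded by their range
  expect_true(all(p1 >= min(yr) & p1 <= max(yr)))
  # and the forest actually learns the signal
  expect_gt(evaluate_predictions(p1, yr)$r2, 0.8)
})

test_that("mlp regressor fits a linear signal and is seed-deterministic", {
  set.seed(51)
  X <- matrix(rnorm(1500), 150, 10)
  y <- X %*% rnorm(10) + rnorm(150, 0, 0.05)
  m1 <- fit_regressor("mpnr", X[1:100, ], y[1:100],
                      list(hidden = "16", epochs = 300L), seed = 2)
  m2 <- fit_regressor("mpnr", X[1:100, ], y[1:100],
                      list(hidden = "16", epochs = 300L), seed = 2)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_gt(evaluate_predictions(predict(m1, X[101:150, ]), y[101:150])$r2,
            0.9)
  # two-hidden-layer spec parses
  m3 <- fit_regressor("mpnr", X[1:100, ], y[1:100],
                      list(hidden = "16,8", epochs = 50L), seed = 2)
  expect_length(m3$W, 3)
})

test_that("family aliases resolve and unknown families error", {
  expect_equal(model_family("rfr")$name, "tree_ensemble_regressor")
  expect_equal(model_family("KNR")$name, "nearest_neighbor_regressor")
  expect_equal(model_family("mlp")$name, "feedforward_network_regressor")
  expect_error(model_family("svm"), "unknown model family")
})

test_that("tune_and_fit evaluates the grid on the held-out split", {
  set.seed(61)
  X <- matrix(rnorm(600), 60, 10)
  y <- X[, 1] + rnorm(60, 0, 0.1)
  fam1 <- model_family("knr", list(k = 3L, weights = "uniform"))
  out <- tune_and_fit(fam1, X[1:48, ], y[1:48], X[49:60, ], y[49:60], seed = 1)
  # single grid point -> it is the best_params
  expect_equal(out$best_params$k, 3L)
  expect_s3_class(out$model, "vs_knn")
  expect_equal(out$test_r2,
               evaluate_predictions(predict(out$model, X[49:60, ]),
                                    y[49:60])$r2)
  # multi-point grid picks the held-out optimum
  fam2 <- model_family("knr", list(k = c(1L, 5L, 40L), weights = "uniform"))
  out2 <- tune_and_fit(fam2, X[1:48, ], y[1:48], X[49:60, ], y[49:60])
  scores <- vapply(c(1L, 5L, 40L), function(k) {
    m <- fit_regressor("knr", X[1:48, ], y[1:48], list(k = k))
    evaluate_predictions(predict(m, X[49:60, ]), y[49:60])$r2
  }, 0)
  expect_equal(out2$best_params$k, c(1L, 5L, 40L)[which.max(scores)])
  expect_error(tune_and_fit(fam1, X[1:5, ], y[1:5], X[49:60, ], y[49:60]),
               ">= 10 training rows")
  # k = 1 exact-match retrieval survives tuning: test point in train set
  fam3 <- model_family("knr", list(k = 1L, weights = "uniform"))
  out3 <- tune_and_fit(fam3, X[1:48, ], y[1:48],
                       X[c(1, 5, 20, 30, 40, 48), ], y[c(1, 5, 20, 30, 40, 48)])
  expect_equal(out3$test_r2, 1)
})
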