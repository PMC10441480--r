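# Regressor families for the property sweep.
#
# Three deliberately diverse weak learners: a bagged regression-tree forest
# (compiled; robust, scale-insensitive), a k-nearest-neighbour regressor
# (similarity-driven, highlights near-identical sequences with divergent
# phenotypes), and a small feedforward network (captures smooth nonlinear
# structure; standardizes its inputs internally since network training is
# scale-sensitive, whereas trees and raw-distance neighbours consume the raw
# encodings). None of the usual CRAN learners (randomForest, nnet, rpart)
# are assumed: the implementations here are self-contained and fully
# seed-deterministic, which the sweep cache relies on.

FAMILY_NAMES <- c("tree_ensemble_regressor", "nearest_neighbor_regressor",
                  "feedforward_network_regressor")

canonical_family <- function(name) {
  alias <- c(tree_ensemble_regressor = "tree_ensemble_regressor",
             rfr = "tree_ensemble_regressor",
             forest = "tree_ensemble_regressor",
             nearest_neighbor_regressor = "nearest_neighbor_regressor",
             knr = "nearest_neighbor_regressor",
             knn = "nearest_neighbor_regressor",
             feedforward_network_regressor = "feedforward_network_regressor",
             mpnr = "feedforward_network_regressor",
             mlp = "feedforward_network_regressor")
  out <- alias[tolower(name)]
  if (anyNA(out)) stopf("unknown model family: %s", name[is.na(out)][1])
  unname(out)
}

#' Define a model family with a hyperparameter grid
#'
#' @param name Family name (`"tree_ensemble_regressor"`,
#'   `"nearest_neighbor_regressor"`, `"feedforward_network_regressor"`;
#'   aliases `rfr`/`knr`/`mpnr` accepted).
#' @param grid Named list of candidate values, crossed exhaustively during
#'   tuning. `NULL` uses the family default grid.
#' @return Object of class `model_family`.
#' @export
model_family <- function(name, grid = NULL) {
  name <- canonical_family(name)
  grid <- grid %||% default_grid(name)
  stopifnot(is.list(grid), length(grid) > 0, !is.null(names(grid)))
  structure(list(name = name, grid = grid), class = "model_family")
}

default_grid <- function(name) {
  switch(name,
    tree_ensemble_regressor =
      list(n_trees = c(100L, 300L, 500L), max_depth = c(0L, 10L, 20L)),
    nearest_neighbor_regressor =
      list(k = c(2L, 5L, 10L, 20L), weights = c("uniform", "distance")),
    feedforward_network_regressor =
      list(hidden = c("64", "128,64"), l2 = c(1e-4, 1e-3)))
}

#' Default model families
#'
#' The three-family sweep default: bagged trees, nearest neighbours,
#' feedforward network, each with a small exhaustive grid over its key knob
#' (tree count/depth, neighbour count/weighting, hidden width/L2).
#'
#' @param grids Optional named list overriding per-family grids.
#' @return List of [model_family()] objects.
#' @export
default_families <- function(grids = NULL) {
  lapply(FAMILY_NAMES, function(nm) model_family(nm, grids[[nm]]))
}

grid_points <- function(family) {
  pts <- expand.grid(family$grid, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(pts)), function(i) as.list(pts[i, , drop = FALSE]))
}

#' Fit one regressor
#'
#' Low-level entry point used by the sweep; most callers want
#' [tune_and_fit()] instead.
#'
#' @param family_name Model family (see [model_family()]).
#' @param X Numeric training matrix (rows = variants).
#' @param y Numeric response.
#' @param params Named list of hyperparameters for this family.
#' @param seed Integer seed controlling all stochastic elements
#'   (bootstrap resampling, network initialization).
#' @return A fitted model object with a `predict()` method.
#' @export
fit_regressor <- function(family_name, X, y, params = list(), seed = 0L) {
  family_name <- canonical_family(family_name)
  X <- as.matrix(X)
  if (!all(is.finite(y))) stopf("non-finite response values")
  switch(family_name,
    tree_ensemble_regressor = fit_forest(X, y, params, seed),
    nearest_neighbor_regressor = fit_knn(X, y, params),
    feedforward_network_regressor = fit_mlp(X, y, params, seed))
}

# ---- bagged regression forest (compiled) ------------------------------------

fit_forest <- function(X, y, params, seed) {
  n_trees <- as.integer(params$n_trees %||% 300L)
  max_depth <- as.integer(params$max_depth %||% 0L)
  mtry <- as.integer(params$mtry %||% max(1L, floor(ncol(X) / 3)))
  min_split <- as.integer(params$min_split %||% 2L)
  min_leaf <- as.integer(params$min_leaf %||% 1L)
  bootstrap <- isTRUE(params$bootstrap %||% TRUE)
  trees <- .forest_fit(X, as.numeric(y), n_trees, mtry, max_depth,
                       min_split, min_leaf, bootstrap, as.integer(seed))
  structure(list(trees = trees, p = ncol(X),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               mtry = mtry, min_split = min_split,
                               min_leaf = min_leaf, bootstrap = bootstrap)),
            class = "vs_forest")
}

#' @export
predict.vs_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stopf("expected %d features, got %d", object$p, ncol(newdata))
  }
  as.numeric(.forest_predict(object$trees, newdata))
}

# ---- k-nearest-neighbour regressor ------------------------------------------

fit_knn <- function(X, y, params) {
  k <- as.integer(params$k %||% 5L)
  weights <- match.arg(params$weights %||% "uniform", c("uniform", "distance"))
  if (k < 1 || k > nrow(X)) stopf("k = %d out of range for %d training rows", k, nrow(X))
  structure(list(X = X, y = as.numeric(y), k = k, weights = weights),
            class = "vs_knn")
}

#' @export
predict.vs_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) {
    stopf("expected %d features, got %d", ncol(object$X), ncol(newdata))
  }
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  d2 <- outer(rowSums(newdata^2), rowSums(object$X^2), `+`) -
    2 * tcrossprod(newdata, object$X)
  d2[d2 < 0] <- 0
  k <- object$k
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]
    if (object$weights == "uniform") {
      mean(object$y[nn])
    } else {
      d <- sqrt(row[nn])
      if (any(d == 0)) return(mean(object$y[nn[d == 0]]))
      w <- 1 / d
      sum(w * object$y[nn]) / sum(w)
    }
  })
}

# ---- feedforward network regressor ------------------------------------------

parse_hidden <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  as.integer(strsplit(as.character(spec), ",", fixed = TRUE)[[1]])
}

fit_mlp <- function(X, y, params, seed) {
  hidden <- parse_hidden(params$hidden %||% "64")
  l2 <- as.numeric(params$l2 %||% 1e-4)
  epochs <- as.integer(params$epochs %||% 500L)
  lr <- as.numeric(params$lr %||% 0.003)

  # internal standardization of X and y (fit on training data only)
  x_mu <- colMeans(X); x_sd <- apply(X, 2, sd); x_sd[x_sd == 0] <- 1
  y_mu <- mean(y); y_sd <- sd(y); if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  ys <- (y - y_mu) / y_sd

  sizes <- c(ncol(X), hidden, 1L)
  n_layers <- length(sizes) - 1L
  init <- withr::with_seed(seed, lapply(seq_len(n_layers), function(l) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))   # Glorot uniform
    list(W = matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  }))
  W <- lapply(init, `[[`, "W"); b <- lapply(init, `[[`, "b")

  # full-batch Adam on MSE + L2
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  relu <- function(z) pmax(z, 0)

  for (epoch in seq_len(epochs)) {
    act <- vector("list", n_layers + 1L)
    act[[1]] <- Xs
    pre <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+")
      pre[[l]] <- z
      act[[l + 1]] <- if (l < n_layers) relu(z) else z
    }
    resid <- act[[n_layers + 1L]][, 1] - ys
    delta <- matrix(2 * resid / n, ncol = 1)
    for (l in rev(seq_len(n_layers))) {
      gW <- crossprod(act[[l]], delta) + 2 * l2 * W[[l]]
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (pre[[l - 1]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^epoch; corr2 <- 1 - beta2^epoch
      W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  structure(list(W = W, b = b, x_mu = x_mu, x_sd = x_sd,
                 y_mu = y_mu, y_sd = y_sd, p = ncol(X),
                 params = list(hidden = hidden, l2 = l2, epochs = epochs, lr = lr)),
            class = "vs_mlp")
}

#' @export
predict.vs_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) {
    stopf("expected %d features, got %d", object$p, ncol(newdata))
  }
  a <- sweep(sweep(newdata, 2, object$x_mu), 2, object$x_sd, "/")
  n_layers <- length(object$W)
  for (l in seq_len(n_layers)) {
    a <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < n_layers) a <- pmax(a, 0)
  }
  as.numeric(a[, 1]) * object$y_sd + object$y_mu
}
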