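# Property sweep and stacked ensemble.
#
# For every (property scale, model family) pair: encode the library with
# the scale, rank features by a univariate score on the training rows, keep
# the top k, run an exhaustive grid search scored by held-out R-squared on
# the fixed test split, and record the best grid point. The sweep therefore
# enumerates |scales| x |families| training runs (1662 for the full
# 554-scale dictionary and three families). Each family's top-n scales by
# test R-squared are stacked into a mean ensemble whose per-contributor
# predictions are retained for downstream significance testing.
#
# Note the grid search is scored on the same held-out split used for final
# reporting (one 80/20 split, no inner CV). That is an optimistic-bias
# choice, kept deliberately; see the methods vignette.

#' Coefficient of determination and mean squared error
#'
#' @param pred Numeric predictions.
#' @param truth Numeric observed values, same length.
#' @return List with `r2` (1 - SS_res/SS_tot; `NA` when the truth has zero
#'   variance) and `mse`.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  list(r2 = r2, mse = mean((truth - pred)^2))
}

#' Univariate feature selection
#'
#' Scores each feature by its univariate association with the response and
#' returns the indices of the top `k`, ordered by decreasing score with
#' ties broken by lowest index. The default score is the F-statistic of the
#' single-feature linear regression, `F = r^2 / (1 - r^2) * (n - 2)`;
#' constant features score 0.
#'
#' @param X Numeric matrix (training rows only — selecting on all rows
#'   would leak the test set).
#' @param y Numeric response with nonzero variance.
#' @param k Number of features to keep, `1 <= k <= ncol(X)`.
#' @param score Scoring function name; only `"f_stat"` is built in.
#' @return Integer vector of `k` column indices.
#' @export
select_features <- function(X, y, k, score = "f_stat") {
  X <- as.matrix(X)
  d <- ncol(X); n <- nrow(X)
  if (k < 1 || k > d) stopf("k = %d out of range 1..%d", k, d)
  if (sd(y) == 0) stopf("constant response: univariate scores undefined")
  score <- match.arg(score, "f_stat")
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[!is.finite(r)] <- 0           # constant features
  r2 <- pmin(r^2, 1 - 1e-15)      # guard exact collinearity
  f <- r2 / (1 - r2) * (n - 2)
  ord <- order(-f, seq_len(d))
  ord[seq_len(k)]
}

sweep_result_row <- function(family, scale_id, best_params, r2, mse, features) {
  data.frame(family = family, scale_id = scale_id,
             best_params = as.character(jsonlite::toJSON(best_params, auto_unbox = TRUE)),
             test_r2 = r2, test_mse = mse,
             selected_features = paste(features, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Grid-search one family on one encoded design
#'
#' Evaluates every grid point of `family` on `(X_train, y_train)`, scores
#' each by R-squared on `(X_test, y_test)`, and refits the best point. A
#' grid point whose fit fails is scored `-Inf` and logged, not fatal.
#'
#' @param family A [model_family()].
#' @param X_train,y_train Training design and response.
#' @param X_test,y_test Held-out design and response used for grid scoring.
#' @param seed Seed forwarded to every fit.
#' @return List with `model` (the refit best model), `best_params`,
#'   `test_r2`, `test_mse`.
#' @export
tune_and_fit <- function(family, X_train, y_train, X_test, y_test, seed = 0L) {
  stopifnot(inherits(family, "model_family"))
  if (nrow(X_train) < 10) stopf("need >= 10 training rows, have %d", nrow(X_train))
  pts <- grid_points(family)
  best <- list(r2 = -Inf, mse = Inf, params = NULL, model = NULL)
  for (params in pts) {
    fitted <- tryCatch(
      fit_regressor(family$name, X_train, y_train, params, seed = seed),
      error = function(e) {
        message(sprintf("grid point failed for %s (%s): %s", family$name,
                        jsonlite::toJSON(params, auto_unbox = TRUE),
                        conditionMessage(e)))
        NULL
      })
    if (is.null(fitted)) next
    ev <- evaluate_predictions(predict(fitted, X_test), y_test)
    r2 <- if (is.na(ev$r2)) -Inf else ev$r2
    if (r2 > best$r2) {
      best <- list(r2 = ev$r2, mse = ev$mse, params = params, model = fitted)
    }
  }
  if (is.null(best$model)) stopf("all grid points failed for %s", family$name)
  list(model = best$model, best_params = best$params,
       test_r2 = best$r2, test_mse = best$mse)
}

#' Enumerate the sweep job table
#'
#' One row per (scale, family) pair — the unit of work of
#' [run_property_sweep()]. With the full 554-scale dictionary and three
#' families this enumerates 1662 training runs.
#'
#' @param dictionary A [property_dictionary()].
#' @param families List of [model_family()] objects.
#' @return data.frame with columns `scale_id`, `family`.
#' @export
sweep_jobs <- function(dictionary, families) {
  fam <- vapply(families, `[[`, "", "name")
  expand.grid(scale_id = scale_ids(dictionary), family = fam,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

sweep_cache_key <- function(split, scale, family, feature_k, seed) {
  digest::digest(list(train = split$train_ids, test = split$test_ids,
                      scale_id = scale$scale_id, values = scale$values,
                      family = family$name, grid = family$grid,
                      feature_k = feature_k, seed = seed))
}

#' Sweep every property scale with every model family
#'
#' The core screening loop: for each complete scale in the dictionary and
#' each family, encode, select features on the training rows, grid-search,
#' and record held-out R-squared and MSE. Results are cached as JSON lines
#' keyed by a content hash of (split, scale, grid, seed), so an interrupted
#' sweep resumes without refitting.
#'
#' @param lib A deduplicated `variant_library`.
#' @param split A `library_split` from [split_train_test()].
#' @param dictionary A [property_dictionary()].
#' @param families List of [model_family()] objects (default all three).
#' @param feature_k Features kept by univariate selection
#'   (default `min(100, L)`).
#' @param seed Seed forwarded to every fit.
#' @param cache_file Optional path to a `sweep.jsonl` cache.
#' @param fit_fun Tuner, by default [tune_and_fit()]; tests may substitute
#'   a mock to count enumerations without fitting.
#' @param verbose Print one line per job.
#' @return data.frame of sweep results, one row per (scale, family), with
#'   columns `family`, `scale_id`, `best_params` (JSON), `test_r2`,
#'   `test_mse`, `selected_features`.
#' @export
run_property_sweep <- function(lib, split, dictionary,
                               families = default_families(),
                               feature_k = NULL, seed = 0L,
                               cache_file = NULL, fit_fun = tune_and_fit,
                               verbose = FALSE) {
  stopifnot(inherits(lib, "variant_library"), inherits(split, "library_split"))
  if (n_scales(dictionary) == 0) stopf("empty property dictionary")
  feature_k <- feature_k %||% min(100L, lib$base$length)

  y <- target_values(lib)
  y_train <- y[split$train_ids]; y_test <- y[split$test_ids]

  cache <- list()
  if (!is.null(cache_file) && file.exists(cache_file)) {
    for (line in readLines(cache_file, warn = FALSE)) {
      rec <- jsonlite::fromJSON(line)
      cache[[rec$key]] <- rec
    }
  }

  rows <- list()
  for (scale in dictionary$scales) {
    em <- encode_property(lib, scale)
    X_train <- em[split$train_ids, , drop = FALSE]
    X_test <- em[split$test_ids, , drop = FALSE]
    feats <- select_features(X_train, y_train, feature_k)
    for (family in families) {
      key <- sweep_cache_key(split, scale, family, feature_k, seed)
      if (!is.null(cache[[key]])) {
        rec <- cache[[key]]
        rows[[length(rows) + 1L]] <- sweep_result_row(
          family$name, scale$scale_id, jsonlite::fromJSON(rec$best_params),
          rec$test_r2, rec$test_mse, rec$selected_features)
        next
      }
      tuned <- fit_fun(family, X_train[, feats, drop = FALSE], y_train,
                       X_test[, feats, drop = FALSE], y_test, seed = seed)
      rows[[length(rows) + 1L]] <- sweep_result_row(
        family$name, scale$scale_id, tuned$best_params,
        tuned$test_r2, tuned$test_mse, feats)
      if (verbose) {
        message(sprintf("%s / %s: R2 = %.3f", scale$scale_id, family$name,
                        tuned$test_r2))
      }
      if (!is.null(cache_file)) {
        rec <- list(key = key, family = family$name, scale_id = scale$scale_id,
                    best_params = as.character(
                      jsonlite::toJSON(tuned$best_params, auto_unbox = TRUE)),
                    test_r2 = tuned$test_r2, test_mse = tuned$test_mse,
                    selected_features = feats)
        cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)),
            "\n", sep = "", file = cache_file, append = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank each family's scales and stack the top performers
#'
#' Per family, scales are ordered by held-out R-squared (descending; ties
#' broken by lexicographically smaller scale id) and the best `top_n` are
#' refit with their winning grid point to become contributor models. With
#' three families and `top_n = 5` the stack holds exactly 15 contributors.
#'
#' @param lib,split,dictionary,families,feature_k,seed As in
#'   [run_property_sweep()].
#' @param sweep Sweep result data.frame from [run_property_sweep()].
#' @param top_n Scales retained per family (default 5).
#' @return Object of class `stacked_ensemble`.
#' @export
build_stacked_ensemble <- function(lib, split, dictionary, sweep,
                                   families = default_families(),
                                   top_n = 5L, feature_k = NULL, seed = 0L) {
  feature_k <- feature_k %||% min(100L, lib$base$length)
  y <- target_values(lib)
  y_train <- y[split$train_ids]; y_test <- y[split$test_ids]
  fam_names <- vapply(families, `[[`, "", "name")

  contributors <- list()
  for (family in families) {
    sub <- sweep[sweep$family == family$name & is.finite(sweep$test_r2), ,
                 drop = FALSE]
    if (nrow(sub) < top_n) {
      stopf("family %s has %d scales with finite R2, need top_n = %d",
            family$name, nrow(sub), top_n)
    }
    sub <- sub[order(-sub$test_r2, sub$scale_id), , drop = FALSE]
    for (i in seq_len(top_n)) {
      scale <- get_scale(dictionary, sub$scale_id[i])
      em <- encode_property(lib, scale)
      X_train <- em[split$train_ids, , drop = FALSE]
      feats <- as.integer(strsplit(sub$selected_features[i], ",")[[1]])
      params <- jsonlite::fromJSON(sub$best_params[i])
      model <- fit_regressor(family$name, X_train[, feats, drop = FALSE],
                             y_train, params, seed = seed)
      contributors[[length(contributors) + 1L]] <- list(
        family = family$name, scale_id = scale$scale_id, scale = scale,
        features = feats, params = params, seed = seed,
        sweep_r2 = sub$test_r2[i], model = model)
    }
  }
  structure(list(contributors = contributors, base = lib$base,
                 target = lib$target, top_n = as.integer(top_n),
                 families = fam_names, feature_k = feature_k),
            class = "stacked_ensemble")
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf("<stacked_ensemble> %d contributors (%d families x top %d), target '%s'\n",
              length(x$contributors), length(x$families), x$top_n, x$target))
  invisible(x)
}

contributor_labels <- function(ensemble) {
  vapply(ensemble$contributors, function(ct) {
    paste(abbreviate_family(ct$family), ct$scale_id, sep = ".")
  }, "")
}

abbreviate_family <- function(name) {
  c(tree_ensemble_regressor = "rfr", nearest_neighbor_regressor = "knr",
    feedforward_network_regressor = "mpnr")[[name]]
}

#' Ensemble predictions with per-contributor detail
#'
#' Each variant receives one prediction per contributor plus their
#' arithmetic mean. The per-contributor columns are retained because the
#' downstream significance test compares the 15 predictions for a mutant
#' against the 15 for the base construct. Predictions are unitless values
#' on the normalized phenotype scale of the training library.
#'
#' @param ensemble A `stacked_ensemble`.
#' @param variants A `variant_library`, a `novel_library`, or a named
#'   character vector of sequences of the training length L.
#' @return data.frame with columns `id`, `mean_prediction`, and one column
#'   per contributor (`rfr.<scale>`, `knr.<scale>`, `mpnr.<scale>`).
#' @export
predict_ensemble <- function(ensemble, variants) {
  stopifnot(inherits(ensemble, "stacked_ensemble"))
  if (inherits(variants, "novel_library")) {
    variants <- setNames(variants$variants$sequence, variants$variants$id)
  }
  seqs <- resolve_sequences(variants)
  if (any(nchar(seqs) != ensemble$base$length)) {
    stopf("variant sequences must have the training length %d",
          ensemble$base$length)
  }
  preds <- matrix(NA_real_, nrow = length(seqs),
                  ncol = length(ensemble$contributors))
  # encode once per distinct scale, not once per contributor
  scale_ids <- vapply(ensemble$contributors, function(ct) ct$scale_id, "")
  encodings <- list()
  for (j in seq_along(ensemble$contributors)) {
    ct <- ensemble$contributors[[j]]
    if (is.null(encodings[[ct$scale_id]])) {
      encodings[[ct$scale_id]] <- encode_property(seqs, ct$scale)
    }
    X <- encodings[[ct$scale_id]][, ct$features, drop = FALSE]
    preds[, j] <- predict(ct$model, X)
  }
  colnames(preds) <- contributor_labels(ensemble)
  data.frame(id = names(seqs), mean_prediction = rowMeans(preds), preds,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
predict.stacked_ensemble <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' Per-family scale ranking from a sweep
#'
#' @param sweep Sweep result data.frame.
#' @return The sweep rows ordered within family by decreasing held-out
#'   R-squared (ties by scale id), with a `rank` column.
#' @export
rank_scales <- function(sweep) {
  parts <- lapply(split(sweep, sweep$family), function(sub) {
    sub <- sub[order(-sub$test_r2, sub$scale_id), , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
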