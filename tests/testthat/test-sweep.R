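test_that("sweep_jobs enumerates |scales| x |families| units of work", {
  dict <- synthetic_dictionary(10, seed = 1)
  jobs <- sweep_jobs(dict, default_families())
  expect_equal(nrow(jobs), 30)
  expect_equal(length(unique(jobs$scale_id)), 10)
  expect_equal(length(unique(jobs$family)), 3)
})

test_that("run_property_sweep produces one result per (scale, family)", {
  setup <- small_sweep_setup()
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict,
                           fast_families(), seed = 1)
  expect_equal(nrow(sw), n_scales(setup$dict) * 3)
  expect_true(all(sw$test_r2 <= 1))
  expect_true(all(sw$test_mse >= 0))
  expect_setequal(unique(sw$family),
                  c("tree_ensemble_regressor", "nearest_neighbor_regressor",
                    "feedforward_network_regressor"))
  # full determinism: identical inputs give identical results
  sw2 <- run_property_sweep(setup$lib, setup$split, setup$dict,
                            fast_families(), seed = 1)
  expect_identical(sw, sw2)
})

test_that("sweep cache resumes without refitting", {
  setup <- small_sweep_setup(n_scales = 2)
  cache <- tempfile(fileext = ".jsonl")
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict,
                           fast_families(), seed = 1, cache_file = cache)
  expect_equal(length(readLines(cache)), nrow(sw))
  # rerun with a tuner that would error if invoked: results must come
  # entirely from the cache
  poison <- function(...) stop("tuner must not run on a warm cache")
  sw2 <- run_property_sweep(setup$lib, setup$split, setup$dict,
                            fast_families(), seed = 1, cache_file = cache,
                            fit_fun = poison)
  expect_equal(sw2[c("family", "scale_id", "test_r2", "test_mse")],
               sw[c("family", "scale_id", "test_r2", "test_mse")])
  # a different seed is a cache miss
  expect_error(run_property_sweep(setup$lib, setup$split, setup$dict,
                                  fast_families(), seed = 2,
                                  cache_file = cache, fit_fun = poison),
               "must not run")
})

test_that("mocked sweep enumerates the full job count without fitting", {
  setup <- small_sweep_setup(n_scales = 6)
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict,
                           default_families(), seed = 1,
                           fit_fun = mock_fit_fun)
  expect_equal(nrow(sw), 18)
})

test_that("build_stacked_ensemble keeps each family's top scales", {
  setup <- small_sweep_setup(n_scales = 4, n_variants = 70)
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict,
                           fast_families(), seed = 1)
  ens <- build_stacked_ensemble(setup$lib, setup$split, setup$dict, sw,
                                fast_families(), top_n = 2, seed = 1)
  expect_length(ens$contributors, 6)
  # contributors per family are that family's two best scales by R2
  for (fam in unique(sw$family)) {
    sub <- sw[sw$family == fam, ]
    best <- sub$scale_id[order(-sub$test_r2, sub$scale_id)][1:2]
    got <- vapply(Filter(function(ct) ct$family == fam, ens$contributors),
                  `[[`, "", "scale_id")
    expect_equal(got, best)
  }
  # top_n = 1 with one family -> 1 contributor
  ens1 <- build_stacked_ensemble(setup$lib, setup$split, setup$dict,
                                 sw[sw$family == "nearest_neighbor_regressor", ],
                                 fast_families()[2], top_n = 1, seed = 1)
  expect_length(ens1$contributors, 1)
  # insufficient finite scales errors
  expect_error(build_stacked_ensemble(setup$lib, setup$split, setup$dict,
                                      sw, fast_families(), top_n = 10),
               "need top_n")
})

test_that("R2 ties at the top_n boundary break lexicographically", {
  setup <- small_sweep_setup(n_scales = 3, n_variants = 60)
  fam <- fast_families()[2]
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict, fam, seed = 1)
  # force a three-way tie: the smaller scale_id must win rank 1
  sw$test_r2 <- 0.5
  ens <- build_stacked_ensemble(setup$lib, setup$split, setup$dict, sw,
                                fam, top_n = 1, seed = 1)
  expect_equal(ens$contributors[[1]]$scale_id, min(sw$scale_id))
})

test_that("predict_ensemble returns per-contributor columns averaging to the mean", {
  setup <- small_sweep_setup(n_scales = 3, n_variants = 70)
  sw <- run_property_sweep(setup$lib, setup$split, setup$dict,
                           fast_families(), seed = 1)
  ens <- build_stacked_ensemble(setup$lib, setup$split, setup$dict, sw,
                                fast_families(), top_n = 2, seed = 1)
  preds <- predict_ensemble(ens, setup$lib)
  expect_equal(nrow(preds), n_variants(setup$lib))
  contrib <- as.matrix(preds[, -(1:2)])
  expect_equal(ncol(contrib), 6)
  expect_equal(preds$mean_prediction, unname(rowMeans(contrib)))
  # the mean lies within the contributor envelope
  expect_true(all(preds$mean_prediction >= apply(contrib, 1, min) - 1e-12))
  expect_true(all(preds$mean_prediction <= apply(contrib, 1, max) + 1e-12))
  # the base construct can be scored as a control alongside novel variants
  ctrl <- predict_ensemble(ens, c(ctrl = setup$lib$base$sequence))
  expect_equal(ctrl$id, "ctrl")
  expect_true(is.finite(ctrl$mean_prediction))
  # sequence length mismatch is a shape error
  expect_error(predict_ensemble(ens, c(x = "ACDEF")), "training length")
})
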