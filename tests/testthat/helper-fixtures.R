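# shared fixtures, all built in code

toy_base <- function(seq = "ACDEF", name = "toy") base_construct(seq, name = name)

# small library over a given base from explicit rows
toy_library <- function(base = toy_base(),
                        rows = data.frame(
                          id = c("v1", "v2", "v3"),
                          mutations = c("D3Y", "A1C;F5W", ""),
                          dff = c(1.2, 0.8, 1.0)),
                        target = "dff") {
  parse_variant_table(rows, base, target)
}

# dictionary with a scale whose values are easy to reason about
unit_scale <- function(id = "UNIT", values = NULL) {
  if (is.null(values)) values <- setNames(seq(0.05, 1, by = 0.05), sort(c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")))
  property_scale(id, values)
}

# AAINDEX-format text with n complete + m incomplete scales, written to a
# temp file; returns the path
write_toy_aaindex <- function(n_complete = 8, n_incomplete = 2,
                              path = tempfile(fileext = ".txt")) {
  set.seed(4242)
  order20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  fmt_rows <- function(v) c(paste(sprintf("%8.3f", v[1:10]), collapse = ""),
                            paste(sprintf("%8.3f", v[11:20]), collapse = ""))
  lines <- character(0)
  for (i in seq_len(n_complete + n_incomplete)) {
    v <- round(rnorm(20), 3)
    rows <- fmt_rows(v)
    if (i > n_complete) rows[1] <- sub("^ *[0-9.-]+", "      NA", rows[1])
    lines <- c(lines, sprintf("H TOY%03d", i), "D toy scale",
               paste("I   ", paste(order20[1:10], order20[11:20], sep = "/",
                                   collapse = "  ")),
               rows, "//")
  }
  writeLines(lines, path)
  path
}

# deterministic mid-size synthetic training setup for sweep tests
small_sweep_setup <- function(n_scales = 4, n_variants = 80, base_length = 30,
                              n_mutable = 10, seed = 5) {
  dict <- synthetic_dictionary(n_scales, seed = seed)
  cfg <- synthetic_library_config(
    base_length = base_length, n_mutable = n_mutable, n_variants = n_variants,
    true_scale_id = scale_ids(dict)[1], noise_sd = 0.3, seed = seed)
  lib <- deduplicate_average(simulate_library(cfg, dict))
  split <- split_train_test(lib, 0.8, 42)
  list(dict = dict, lib = lib, split = split)
}

# one-point grids so sweep tests stay fast
fast_families <- function() {
  default_families(list(
    tree_ensemble_regressor = list(n_trees = 60L, max_depth = 0L),
    nearest_neighbor_regressor = list(k = 3L, weights = "distance"),
    feedforward_network_regressor = list(hidden = "16", l2 = 1e-3,
                                         epochs = 150L)))
}

# mock tuner: deterministic pseudo-R2 without any model fitting
mock_fit_fun <- function(family, X_train, y_train, X_test, y_test, seed = 0L) {
  list(model = NULL,
       best_params = list(mock = TRUE),
       test_r2 = sum(X_train[1, ]) %% 1,
       test_mse = 1)
}
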