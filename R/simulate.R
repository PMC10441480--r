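# Synthetic genotype-phenotype libraries and fluorescence traces.
#
# The library generator stands in for real indicator mutation libraries:
# point mutants (occasionally multi-mutants) scattered over a fixed set of
# mutable positions of a base construct, with a phenotype that is additive
# in the deltas of one "true" property scale at the mutated positions plus
# Gaussian noise. Additivity is the simplest structure the property
# encoding can represent exactly, which makes the generator a clean
# parameter-recovery target for the sweep: the true scale should rank
# first, decoy scales should not. A pairwise epistatic term is available
# for stress testing. The trace generator emits a flat baseline, an
# instantaneous rise, and an exponential decay with known lambda.

#' Synthetic library configuration
#'
#' @param base_length Residues in the synthetic base construct (default
#'   451, the length of the GCaMP-style scaffold the toolkit targets).
#' @param n_mutable Number of mutable positions (default 75), drawn
#'   uniformly from the construct under `seed` unless `mutable_positions`
#'   is given.
#' @param mutable_positions Optional explicit positions.
#' @param n_variants Variants to draw (default 600).
#' @param true_scale_id Scale (by id, resolved in the supplied dictionary)
#'   that truly drives the phenotype.
#' @param effect_size Phenotype units per property-scale unit (default 1).
#' @param intercept Phenotype of the unmutated base (default 1, the value
#'   of the normalization reference).
#' @param noise_sd Gaussian noise sd; `NULL` (default) means 10% of the
#'   single-substitution effect range, i.e.
#'   `0.1 * 2 * effect_size * (max(scale) - min(scale))` — the span of
#'   phenotype effects a single substitution can produce under the true
#'   scale.
#' @param multi_mutation_rate Probability that a variant carries a second
#'   (and rarely a third) mutation (default 0.2, echoing libraries
#'   dominated by single and double mutants).
#' @param seed RNG seed; the whole library is a pure function of the
#'   configuration.
#' @return Object of class `synthetic_library_config`.
#' @export
synthetic_library_config <- function(base_length = 451L, n_mutable = 75L,
                                     mutable_positions = NULL,
                                     n_variants = 600L, true_scale_id,
                                     effect_size = 1, intercept = 1,
                                     noise_sd = NULL,
                                     multi_mutation_rate = 0.2,
                                     seed = 1L) {
  stopifnot(multi_mutation_rate >= 0, multi_mutation_rate < 1)
  structure(list(base_length = as.integer(base_length),
                 n_mutable = as.integer(n_mutable),
                 mutable_positions = mutable_positions,
                 n_variants = as.integer(n_variants),
                 true_scale_id = true_scale_id,
                 effect_size = effect_size, intercept = intercept,
                 noise_sd = noise_sd,
                 multi_mutation_rate = multi_mutation_rate,
                 seed = as.integer(seed)),
            class = "synthetic_library_config")
}

#' Random amino-acid sequence
#'
#' @param length Residue count.
#' @param seed RNG seed.
#' @return Amino-acid string (uniform over the 20 canonical letters).
#' @export
synthetic_base_sequence <- function(length, seed = 1L) {
  paste(withr::with_seed(seed, sample(AA_ALPHABET, length, replace = TRUE)),
        collapse = "")
}

#' Synthetic property dictionary
#'
#' `n_scales` random scales, optionally with supplied real scales
#' prepended. By default the random scales are iid standard normal
#' (maximally uninformative decoys). Real property databases are not like
#' that: published indices are strongly intercorrelated (the packaged
#' hydropathy and hydrophilicity indices correlate at |r| ~ 0.8), so a
#' dictionary emulating one should contain near-synonyms of the driving
#' property as well as unrelated indices. Supplying `correlations` builds
#' decoy i as `rho_i * z(reference) + sqrt(1 - rho_i^2) * noise`, where the
#' reference is the first scale in `scales`. Scale ids are `SYNTH001, ...`
#' and descriptions mark them as synthetic.
#'
#' @param n_scales Number of random scales.
#' @param scales Optional list of [property_scale()] objects to include
#'   first (e.g. the true scale driving a simulation).
#' @param correlations Optional numeric vector (length `n_scales`, values
#'   in \[-1, 1\]): target correlation of each random scale with the first
#'   scale in `scales`.
#' @param seed RNG seed.
#' @return A [property_dictionary()].
#' @export
synthetic_dictionary <- function(n_scales, scales = list(),
                                 correlations = NULL, seed = 1L) {
  ref <- NULL
  if (!is.null(correlations)) {
    stopifnot(length(correlations) == n_scales, all(abs(correlations) <= 1),
              length(scales) >= 1)
    v <- scales[[1]]$values
    ref <- (v - mean(v)) / sd(v)
  }
  synth <- withr::with_seed(seed, lapply(seq_len(n_scales), function(i) {
    noise <- rnorm(20)
    vals <- if (is.null(ref)) {
      noise
    } else {
      rho <- correlations[i]
      z <- (noise - mean(noise)) / sd(noise)
      z <- z - ref * sum(z * ref) / sum(ref^2)   # orthogonalize to reference
      z <- z / sd(z)
      rho * ref + sqrt(1 - rho^2) * z
    }
    property_scale(sprintf("SYNTH%03d", i), setNames(vals, AA_ALPHABET),
                   "synthetic random scale (not a published index)")
  }))
  property_dictionary(c(scales, synth), provenance = "synthetic")
}

#' Simulate a genotype-phenotype library
#'
#' Draws random (mostly single-point) mutants over the mutable positions
#' and assigns phenotypes
#' `intercept + effect_size * sum(scale[alt] - scale[ref]) + N(0, noise_sd)`
#' where the sum runs over the variant's mutated positions and `scale` is
#' the true property scale. The unmutated base construct is included as a
#' record with its noiseless value (`intercept`). Duplicate mutant draws
#' are collapsed before returning, so the library is ready to split.
#'
#' @param config A [synthetic_library_config()].
#' @param dictionary A [property_dictionary()] containing
#'   `config$true_scale_id`.
#' @return A `variant_library` with target `"phenotype"`; attributes
#'   `mutable_positions`, `noise_sd` (the value actually used), and
#'   `signal_range` record the realized simulation.
#' @export
simulate_library <- function(config, dictionary) {
  stopifnot(inherits(config, "synthetic_library_config"))
  scale <- get_scale(dictionary, config$true_scale_id)
  withr::with_seed(config$seed, {
    base <- base_construct(
      paste(sample(AA_ALPHABET, config$base_length, replace = TRUE),
            collapse = ""),
      name = "synthetic_base")
    positions <- config$mutable_positions %||%
      sort(sample.int(config$base_length, config$n_mutable))
    chars <- strsplit(base$sequence, "", fixed = TRUE)[[1]]

    draw_variant <- function() {
      extra <- stats::rbinom(1, 1, config$multi_mutation_rate) +
        stats::rbinom(1, 1, config$multi_mutation_rate / 4)
      n_mut <- 1L + extra
      pos <- positions[sample.int(length(positions),
                                  min(n_mut, length(positions)))]
      alt <- vapply(pos, function(p) sample(setdiff(AA_ALPHABET, chars[p]), 1), "")
      data.frame(pos = sort(pos), ref = chars[sort(pos)],
                 alt = alt[order(pos)], stringsAsFactors = FALSE)
    }

    # rejection-sample distinct mutants until n_variants unique are in hand
    muts <- list()
    seen <- character(0)
    attempts <- 0L
    max_attempts <- 50L * config$n_variants
    while (length(muts) < config$n_variants && attempts < max_attempts) {
      attempts <- attempts + 1L
      m <- draw_variant()
      key <- format_mutations(m)
      if (!nzchar(key) || key %in% seen) next
      seen <- c(seen, key)
      muts[[length(muts) + 1L]] <- m
    }
    mut_strings <- vapply(muts, format_mutations, "")
    if (length(muts) < config$n_variants) {
      warning(sprintf("mutant space exhausted: %d unique variants of %d requested",
                      length(muts), config$n_variants), call. = FALSE)
    }
    signal <- vapply(muts, function(m) {
      config$intercept + config$effect_size *
        sum(scale$values[m$alt] - scale$values[m$ref])
    }, 0)
    # effect range: a single substitution can shift the phenotype by at most
    # +/- effect_size * (max - min) of the true scale
    effect_range <- 2 * abs(config$effect_size) * diff(range(scale$values))
    noise_sd <- config$noise_sd %||% (0.1 * effect_range)
    phen <- signal + rnorm(length(signal), 0, noise_sd)

    variants <- data.frame(
      id = sprintf("var%04d", seq_along(muts)),
      mutations = mut_strings,
      sequence = vapply(muts, function(m) apply_mutations(base, m), ""),
      phenotype = phen, stringsAsFactors = FALSE)
    # the base construct enters with its noiseless value
    variants <- rbind(variants,
                      data.frame(id = "base", mutations = "",
                                 sequence = base$sequence,
                                 phenotype = config$intercept,
                                 stringsAsFactors = FALSE))
    lib <- new_variant_library(base, variants, "phenotype")
    attr(lib, "mutable_positions") <- positions
    attr(lib, "noise_sd") <- noise_sd
    attr(lib, "signal_range") <- range(signal)
    lib
  })
}

#' Synthetic trace configuration
#'
#' @param baseline_level Baseline intensity (a.u.), default 1.
#' @param peak_dff_percent Peak dF/F0 in percent, default 100.
#' @param lambda Decay constant per second, default 0.5.
#' @param sampling_rate_hz Samples per second, default 10.
#' @param duration_s Total duration, default 20 s.
#' @param baseline_window Baseline sample count, default 50.
#' @param noise_sd Additive Gaussian noise sd (a.u.), default 0.
#' @param seed RNG seed.
#' @export
synthetic_trace_config <- function(baseline_level = 1, peak_dff_percent = 100,
                                   lambda = 0.5, sampling_rate_hz = 10,
                                   duration_s = 20, baseline_window = 50L,
                                   noise_sd = 0, seed = 1L) {
  structure(list(baseline_level = baseline_level,
                 peak_dff_percent = peak_dff_percent, lambda = lambda,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 baseline_window = as.integer(baseline_window),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_trace_config")
}

#' Simulate a fluorescence trace
#'
#' Flat baseline for `baseline_window` samples, instantaneous rise to the
#' peak (`baseline * (1 + peak_dff/100)`), exponential decay with the
#' configured lambda, plus optional Gaussian noise.
#'
#' @param config A [synthetic_trace_config()].
#' @return A [fluorescence_trace()].
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "synthetic_trace_config"))
  dt <- 1 / config$sampling_rate_hz
  times <- seq(0, config$duration_s, by = dt)
  n <- length(times)
  bw <- config$baseline_window
  if (bw >= n - 3) stopf("duration too short for the baseline window")
  peak <- config$baseline_level * (1 + config$peak_dff_percent / 100)
  intensities <- numeric(n)
  intensities[seq_len(bw)] <- config$baseline_level
  t_decay <- times[seq.int(bw + 1L, n)] - times[bw + 1L]
  intensities[seq.int(bw + 1L, n)] <- config$baseline_level +
    (peak - config$baseline_level) * exp(-config$lambda * t_decay)
  if (config$noise_sd > 0) {
    intensities <- intensities +
      withr::with_seed(config$seed, rnorm(n, 0, config$noise_sd))
  }
  fluorescence_trace(times, intensities, baseline_window = bw)
}
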