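# Statistical analysis of ensemble predictions.
#
# The downstream screen works on the per-contributor prediction table:
# predicted change from the base construct, an unpaired t-test of each
# mutant's contributor predictions against the base construct's, sigma
# bands on -log10 p for flagging outliers, and per-residue prevalence in
# the top/bottom extremes of each contributor's ranking. The contributor
# predictions are not independent samples, so these p-values are heuristic
# ranking scores, not calibrated inference; they are used descriptively
# (volcano plots), never corrected for multiple testing.

P_FLOOR <- 1e-300

#' Predicted change from the base construct
#'
#' @param mean_prediction Mean ensemble prediction(s) for mutant(s).
#' @param base_mean Mean ensemble prediction for the base construct.
#' @return `mean_prediction - base_mean` (unitless, normalized scale).
#' @export
predicted_change <- function(mean_prediction, base_mean) {
  mean_prediction - base_mean
}

#' Unpaired two-sided t-test of contributor predictions
#'
#' Student's pooled-variance t by default (`var_equal = TRUE`), with
#' `df = n1 + n2 - 2`; Welch available by flag. Degenerate zero-variance
#' input yields p = 1 for equal means and the floor p otherwise.
#'
#' @param x,y Numeric vectors (e.g. the 15 contributor predictions for a
#'   mutant and for the base construct), each of length >= 2.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return List with `t_statistic`, `p_value`, `df`.
#' @export
test_vs_base <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_statistic = 0, p_value = 1, df = n1 + n2 - 2))
    }
    message("zero pooled variance with unequal means: p floored")
    return(list(t_statistic = sign(mean(x) - mean(y)) * Inf,
                p_value = P_FLOOR, df = n1 + n2 - 2))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (mean(x) - mean(y)) / se
  p <- 2 * pt(-abs(t_stat), df)
  list(t_statistic = t_stat, p_value = max(p, P_FLOOR), df = df)
}

#' Sigma band of a sample
#'
#' Sample mean +/- k standard deviations (ddof = 1). With k = 3 the band
#' covers ~99.7% of a normal sample; values outside it are flagged as
#' extreme (e.g. on -log10 p in a volcano plot).
#'
#' @param values Numeric vector, length >= 2.
#' @param k Band half-width in standard deviations (default 3).
#' @return List with `mean`, `sd`, `k`, `lower`, `upper`.
#' @export
sigma_band <- function(values, k = 3) {
  stopifnot(length(values) >= 2)
  m <- mean(values); s <- sd(values)
  list(mean = m, sd = s, k = k, lower = m - k * s, upper = m + k * s)
}

#' Per-variant delta/significance table (volcano table)
#'
#' Computes, for every variant in a per-contributor prediction table, the
#' predicted change from the base construct, the unpaired t-test of its
#' contributor predictions against the base construct's, -log10 p (p
#' floored at 1e-300), and flags against the +/- k sigma band of the
#' -log10 p distribution.
#'
#' @param preds Prediction data.frame from [predict_ensemble()] (columns
#'   `id`, `mean_prediction`, one column per contributor).
#' @param base_id Id of the base-construct control row within `preds`.
#' @param sigma_k Band half-width (default 3).
#' @param var_equal Passed to [test_vs_base()].
#' @return data.frame with columns `id`, `delta`, `t_statistic`, `p_value`,
#'   `neg_log10_p`, `outside_band` (the base row is excluded).
#' @export
delta_significance <- function(preds, base_id, sigma_k = 3, var_equal = TRUE) {
  i_base <- match(base_id, preds$id)
  if (is.na(i_base)) stopf("base id '%s' not found in predictions", base_id)
  contrib_cols <- setdiff(names(preds), c("id", "mean_prediction"))
  if (length(contrib_cols) < 2) stopf("need >= 2 contributor columns")
  base_preds <- as.numeric(preds[i_base, contrib_cols])
  base_mean <- preds$mean_prediction[i_base]

  rows <- preds[-i_base, , drop = FALSE]
  tt <- lapply(seq_len(nrow(rows)), function(i) {
    test_vs_base(as.numeric(rows[i, contrib_cols]), base_preds,
                 var_equal = var_equal)
  })
  out <- data.frame(
    id = rows$id,
    delta = predicted_change(rows$mean_prediction, base_mean),
    t_statistic = vapply(tt, `[[`, 0, "t_statistic"),
    p_value = vapply(tt, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p_value)
  band <- sigma_band(out$neg_log10_p, k = sigma_k)
  out$outside_band <- out$neg_log10_p < band$lower | out$neg_log10_p > band$upper
  attr(out, "sigma_band") <- band
  out
}

#' Residue prevalence in prediction extremes
#'
#' For each contributor model independently, ranks its predictions over the
#' novel library and takes the `ceiling(fraction * n)` highest and lowest
#' variants; each pick increments the count of the variant's mutated
#' position. In `mode = "ensemble_mean"` the single mean-prediction column
#' is ranked instead.
#'
#' @param preds Prediction data.frame from [predict_ensemble()] over a
#'   single-point library (no base row).
#' @param positions Integer vector: the mutated position of each variant in
#'   `preds` (same order).
#' @param fraction Extreme-tail fraction in (0, 0.5); default 0.025.
#' @param mode `"per_contributor"` (default) or `"ensemble_mean"`.
#' @return data.frame with columns `position`, `top_count`, `bottom_count`,
#'   `total_count`, `share` (fraction of all extreme picks at that
#'   position). Attribute `n_picks_per_ranking` records ceil(fraction * n).
#' @export
prevalence_counts <- function(preds, positions, fraction = 0.025,
                              mode = c("per_contributor", "ensemble_mean")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 0.5, nrow(preds) == length(positions))
  cols <- if (mode == "per_contributor") {
    setdiff(names(preds), c("id", "mean_prediction"))
  } else {
    "mean_prediction"
  }
  n <- nrow(preds)
  m <- ceiling(fraction * n)
  all_pos <- sort(unique(positions))
  top <- setNames(rep(0L, length(all_pos)), all_pos)
  bottom <- top
  for (col in cols) {
    ord <- order(preds[[col]], seq_len(n))   # ties by row order
    lo <- positions[ord[seq_len(m)]]
    hi <- positions[ord[seq.int(n - m + 1L, n)]]
    bottom_tab <- table(factor(lo, levels = all_pos))
    top_tab <- table(factor(hi, levels = all_pos))
    bottom <- bottom + as.integer(bottom_tab)
    top <- top + as.integer(top_tab)
  }
  out <- data.frame(position = all_pos, top_count = as.integer(top),
                    bottom_count = as.integer(bottom))
  out$total_count <- out$top_count + out$bottom_count
  out$share <- out$total_count / sum(out$total_count)
  attr(out, "n_picks_per_ranking") <- m
  attr(out, "n_rankings") <- length(cols)
  out
}

#' Share of a library mutated at a given position
#'
#' The percentage of variants in a library whose mutation set touches the
#' position — e.g. in a 75-position saturation library of 1423 novel
#' variants, any single position accounts for only ~1.3% of the library.
#'
#' @param novel A `novel_library` or data.frame with a `position` column.
#' @param position Construct-numbering position.
#' @return Percentage (0-100).
#' @export
position_share <- function(novel, position) {
  df <- if (inherits(novel, "novel_library")) novel$variants else novel
  100 * sum(df$position == position) / nrow(df)
}

#' Write a volcano table as CSV
#' @param volcano data.frame from [delta_significance()].
#' @param path Output path.
#' @export
write_volcano_csv <- function(volcano, path) {
  write.csv(volcano, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
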