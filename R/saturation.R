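# In-silico single-point saturation mutagenesis.
#
# Candidate generation is wild-type inclusive: every chosen position is
# substituted with all 20 amino acids, giving 20 x |positions| candidates
# (1500 for the canonical 75-position screen). Redundancy removal then
# drops the per-position wild-type candidates (sequence identical to the
# base) and any candidate whose full sequence already occurs in the
# characterized library, leaving only genuinely novel variants (1423 in
# the canonical screen, after 75 base-identical and 2 previously
# characterized removals).

#' Generate saturation-mutagenesis candidates
#'
#' @param base A [base_construct()].
#' @param positions Integer positions (construct numbering) to saturate;
#'   must be unique and in range.
#' @return data.frame with columns `id` (mutation-string id such as
#'   `"L317H"`), `mutations`, `position`, `sequence`;
#'   `20 * length(positions)` rows.
#' @export
generate_saturation <- function(base, positions) {
  stopifnot(inherits(base, "base_construct"))
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stopf("saturation positions must be unique")
  idx <- positions - base$offset + 1L
  if (any(idx < 1L | idx > base$length)) {
    stopf("position(s) out of range: %s",
          paste(positions[idx < 1L | idx > base$length], collapse = ", "))
  }
  chars <- strsplit(base$sequence, "", fixed = TRUE)[[1]]
  rows <- vector("list", length(positions) * 20L)
  r <- 0L
  for (i in seq_along(positions)) {
    ref <- chars[idx[i]]
    for (aa in AA_ALPHABET) {
      r <- r + 1L
      mutated <- chars
      mutated[idx[i]] <- aa
      rows[[r]] <- data.frame(
        id = paste0(ref, positions[i], aa),
        mutations = if (aa == ref) "" else paste0(ref, positions[i], aa),
        position = positions[i],
        sequence = paste(mutated, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove redundant saturation candidates
#'
#' Drops candidates whose full sequence equals the base construct (the
#' wild-type candidate at each position) or matches any sequence in the
#' characterized library. Matching is on full sequence identity, never on
#' ids or mutation strings.
#'
#' @param candidates data.frame from [generate_saturation()].
#' @param base A [base_construct()].
#' @param characterized Optional `variant_library` of previously
#'   characterized variants (full lifted sequences).
#' @return Object of class `novel_library`: `variants` (data.frame),
#'   `removed_base_identical` (count), `removed_previously_characterized`
#'   (id vector).
#' @export
remove_redundant <- function(candidates, base, characterized = NULL) {
  stopifnot(inherits(base, "base_construct"))
  base_identical <- candidates$sequence == base$sequence
  kept <- candidates[!base_identical, , drop = FALSE]
  removed_char <- character(0)
  if (!is.null(characterized)) {
    stopifnot(inherits(characterized, "variant_library"))
    hit <- kept$sequence %in% characterized$variants$sequence
    removed_char <- kept$id[hit]
    kept <- kept[!hit, , drop = FALSE]
  }
  dup <- duplicated(kept$sequence)
  kept <- kept[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(variants = kept,
                 removed_base_identical = sum(base_identical),
                 removed_previously_characterized = removed_char,
                 base = base),
            class = "novel_library")
}

#' @export
print.novel_library <- function(x, ...) {
  cat(sprintf(
    "<novel_library> %d novel variants (removed %d base-identical, %d previously characterized)\n",
    nrow(x$variants), x$removed_base_identical,
    length(x$removed_previously_characterized)))
  invisible(x)
}

#' Build and pre-screen a saturation library in one call
#'
#' @inheritParams generate_saturation
#' @inheritParams remove_redundant
#' @return A `novel_library`.
#' @export
saturation_library <- function(base, positions, characterized = NULL) {
  remove_redundant(generate_saturation(base, positions), base,
                   characterized = characterized)
}

#' Write a novel library and its removal report
#'
#' @param novel A `novel_library`.
#' @param csv_path Output CSV (`id`, `mutations`, `position`, `sequence`).
#' @param report_path Optional JSON removal report.
#' @export
write_novel_library <- function(novel, csv_path, report_path = NULL) {
  write.csv(novel$variants, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(n_novel = nrow(novel$variants),
           removed_base_identical = novel$removed_base_identical,
           removed_previously_characterized =
             novel$removed_previously_characterized),
      report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
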