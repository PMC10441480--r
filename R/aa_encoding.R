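# Numeric encodings of residue sequences.
#
# Three encodings are supported: property (one physicochemical value per
# residue, looked up in an AAINDEX-style scale), label (a seeded random
# bijection of the 20 amino acids onto 0..19), and one-hot (20 indicator
# columns per position). Property encoding is the workhorse: each scale in
# the dictionary gives a different numeric view of the same sequences, and
# the sweep ranks scales by how well models trained on them generalize.

#' Construct a property scale
#'
#' @param scale_id Accession or name (AAINDEX-style, e.g. "KYTJ820101").
#' @param values Named numeric vector, names = one-letter amino-acid codes.
#' @param description Free-text description.
#' @return Object of class `property_scale`. A scale is *complete* when it
#'   has a finite value for all 20 canonical amino acids; only complete
#'   scales may be used for encoding.
#' @export
property_scale <- function(scale_id, values, description = "") {
  stopifnot(is.character(scale_id), length(scale_id) == 1)
  values <- values[names(values) %in% AA_ALPHABET]
  full <- setNames(rep(NA_real_, 20), AA_ALPHABET)
  full[names(values)] <- as.numeric(values)
  structure(list(scale_id = scale_id, description = description,
                 values = full, complete = all(is.finite(full))),
            class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("<property_scale> %s%s: %s\n", x$scale_id,
              if (x$complete) "" else " (incomplete)", x$description))
  invisible(x)
}

#' Construct a property dictionary
#'
#' Incomplete scales (missing a value for any amino acid) are excluded:
#' they cannot encode arbitrary sequences.
#'
#' @param scales List of [property_scale()] objects.
#' @param provenance Free-text provenance note.
#' @return Object of class `property_dictionary` holding only complete
#'   scales, with attributes `n_parsed` and `n_retained`.
#' @export
property_dictionary <- function(scales, provenance = "") {
  stopifnot(all(vapply(scales, inherits, TRUE, "property_scale")))
  ids <- vapply(scales, `[[`, "", "scale_id")
  if (anyDuplicated(ids)) stopf("duplicated scale ids in dictionary")
  complete <- vapply(scales, `[[`, TRUE, "complete")
  kept <- scales[complete]
  if (!all(complete)) {
    message(sprintf("excluded %d incomplete scale(s): %s",
                    sum(!complete), paste(ids[!complete], collapse = ", ")))
  }
  structure(list(scales = setNames(kept, ids[complete]),
                 provenance = provenance),
            class = "property_dictionary",
            n_parsed = length(scales), n_retained = length(kept))
}

#' @export
print.property_dictionary <- function(x, ...) {
  cat(sprintf("<property_dictionary> %d complete scales (%d parsed)%s\n",
              length(x$scales), attr(x, "n_parsed"),
              if (nzchar(x$provenance)) paste0(" - ", x$provenance) else ""))
  invisible(x)
}

#' Number of scales / scale ids in a dictionary
#' @param dict A `property_dictionary`.
#' @rdname dictionary_accessors
#' @export
n_scales <- function(dict) length(dict$scales)

#' @rdname dictionary_accessors
#' @export
scale_ids <- function(dict) names(dict$scales)

#' @param scale_id Scale accession.
#' @rdname dictionary_accessors
#' @export
get_scale <- function(dict, scale_id) {
  s <- dict$scales[[scale_id]]
  if (is.null(s)) stopf("scale '%s' not in dictionary", scale_id)
  s
}

#' Parse an AAINDEX-1 flat file
#'
#' Reads the classic AAINDEX-1 record grammar: `H` accession line, `D`
#' description line(s), and an `I` line followed by two rows of ten values
#' in the canonical A R N D C Q E G H I / L K M F P S T W Y V order.
#' Missing values (`NA`, `-`, empty) mark a scale incomplete; incomplete
#' scales are parsed but excluded from the returned dictionary. The full
#' public AAINDEX release holds 566 indices of which 554 are complete; a
#' small curated fixture ships with the package (see
#' [default_property_dictionary()]) so no download is needed.
#'
#' @param path Path to an AAINDEX-1 format text file.
#' @param provenance Provenance note stored on the dictionary.
#' @return A [property_dictionary()] of the complete scales.
#' @export
read_aaindex <- function(path, provenance = path) {
  lines <- readLines(path, warn = FALSE)
  scales <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "H ")) { i <- i + 1L; next }
    acc <- trimws(sub("^H ", "", lines[i]))
    desc <- ""
    vals <- NULL
    j <- i + 1L
    while (j <= n && !startsWith(lines[j], "//")) {
      if (startsWith(lines[j], "D ")) {
        desc <- trimws(sub("^D ", "", lines[j]))
      } else if (startsWith(lines[j], "I ")) {
        if (j + 2L > n) stopf("truncated value block in scale %s", acc)
        toks <- unlist(strsplit(trimws(c(lines[j + 1L], lines[j + 2L])), "\\s+"))
        if (length(toks) != 20) {
          stopf("malformed value block in scale %s: expected 20 values, got %d",
                acc, length(toks))
        }
        toks[toks %in% c("NA", "-", ".")] <- NA
        vals <- suppressWarnings(as.numeric(toks))
        names(vals) <- AAINDEX_ORDER
        j <- j + 2L
      }
      j <- j + 1L
    }
    if (is.null(vals)) stopf("scale %s has no I value block", acc)
    scales[[length(scales) + 1L]] <- property_scale(acc, vals, desc)
    i <- j + 1L
  }
  if (length(scales) == 0) stopf("no AAINDEX records found in '%s'", path)
  dict <- property_dictionary(scales, provenance = provenance)
  message(sprintf("parsed %d scales, retained %d complete",
                  attr(dict, "n_parsed"), attr(dict, "n_retained")))
  dict
}

#' Packaged property dictionary fixture
#'
#' Loads the curated AAINDEX-1 format fixture shipped under
#' `inst/extdata/aaindex_mini_synthetic.txt`: a handful of canonical
#' published indices (hydropathy, hydrophilicity, polarity, residue mass)
#' plus synthetic stand-in scales, adequate for desk-scale sweeps and tests.
#'
#' @return A [property_dictionary()].
#' @export
default_property_dictionary <- function() {
  path <- system.file("extdata", "aaindex_mini_synthetic.txt",
                      package = "varsweep", mustWork = TRUE)
  suppressMessages(read_aaindex(path, provenance = "packaged fixture (partly synthetic)"))
}

#' Write a property dictionary as JSON
#' @param dict A `property_dictionary`.
#' @param path Output path.
#' @export
write_dictionary_json <- function(dict, path) {
  payload <- list(
    provenance = dict$provenance,
    scales = lapply(unname(dict$scales), function(s) {
      list(scale_id = s$scale_id, description = s$description,
           values = as.list(s$values))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_sequences <- function(x) {
  if (inherits(x, "variant_library")) {
    setNames(x$variants$sequence, x$variants$id)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else {
    stopf("expected a variant_library or character vector of sequences")
  }
}

new_encoded_matrix <- function(mat, ids, kind, feature_names) {
  dimnames(mat) <- list(ids, feature_names)
  structure(mat, encoding = kind, class = c("encoded_matrix", class(mat)))
}

#' Encode sequences with a property scale
#'
#' Cell (i, j) is the scale value of variant i's residue at position j;
#' the matrix is n x L.
#'
#' @param x A `variant_library` or named character vector of equal-length
#'   sequences.
#' @param scale A complete [property_scale()].
#' @return Numeric matrix (class `encoded_matrix`) with variant ids as row
#'   names and `pos<k>` feature columns.
#' @export
encode_property <- function(x, scale) {
  stopifnot(inherits(scale, "property_scale"))
  if (!scale$complete) stopf("scale '%s' is incomplete; cannot encode", scale$scale_id)
  seqs <- resolve_sequences(x)
  cm <- seq_char_matrix(seqs)
  offset <- if (inherits(x, "variant_library")) x$base$offset else 1L
  mat <- matrix(scale$values[cm], nrow = nrow(cm), ncol = ncol(cm))
  new_encoded_matrix(mat, names(seqs), "property",
                     paste0("pos", seq_len(ncol(cm)) + offset - 1L))
}

#' Encode sequences with seeded random integer labels
#'
#' Assigns a seed-deterministic bijection of the 20 amino acids onto the
#' integers 0..19 and applies it elementwise (the "dummy label" baseline
#' encoding).
#'
#' @inheritParams encode_property
#' @param seed RNG seed for the bijection.
#' @return n x L integer-valued `encoded_matrix`.
#' @export
encode_label <- function(x, seed = 0L) {
  seqs <- resolve_sequences(x)
  cm <- seq_char_matrix(seqs)
  offset <- if (inherits(x, "variant_library")) x$base$offset else 1L
  codes <- setNames(withr::with_seed(seed, sample(0:19)), AA_ALPHABET)
  mat <- matrix(codes[cm], nrow = nrow(cm), ncol = ncol(cm))
  new_encoded_matrix(mat, names(seqs), "label",
                     paste0("pos", seq_len(ncol(cm)) + offset - 1L))
}

#' One-hot encode sequences
#'
#' 20 indicator columns per position, position-major with amino acids in
#' fixed alphabetical order (`pos1_A, pos1_C, ..., pos1_Y, pos2_A, ...`);
#' exactly one 1 per (variant, position) block, so each row sums to L.
#'
#' @inheritParams encode_property
#' @return n x 20L `encoded_matrix`.
#' @export
encode_onehot <- function(x) {
  seqs <- resolve_sequences(x)
  cm <- seq_char_matrix(seqs)
  offset <- if (inherits(x, "variant_library")) x$base$offset else 1L
  n <- nrow(cm); L <- ncol(cm)
  aa_idx <- matrix(match(cm, AA_ALPHABET), nrow = n)
  mat <- matrix(0, nrow = n, ncol = 20L * L)
  cols <- (rep(seq_len(L), each = n) - 1L) * 20L + as.vector(aa_idx)
  mat[cbind(rep(seq_len(n), times = L), cols)] <- 1
  feature_names <- as.vector(t(outer(seq_len(L) + offset - 1L, AA_ALPHABET,
                                     function(p, a) paste0("pos", p, "_", a))))
  new_encoded_matrix(mat, names(seqs), "onehot", feature_names)
}

#' Write an encoded matrix as CSV
#' @param em An `encoded_matrix`.
#' @param path Output path.
#' @export
write_encoded_csv <- function(em, path) {
  df <- data.frame(id = rownames(em), as.data.frame(unclass(em)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
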