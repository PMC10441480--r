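# Variant libraries defined as mutation lists against a base construct.
#
# The central data structure mirrors the field's convention for
# genotype-phenotype libraries: each variant carries an id, a mutation
# string such as "L317H;Q305D" (positions in construct numbering), the
# lifted full-length sequence, and one or more normalized phenotype values
# (e.g. 1 AP dF/F0, 10 AP decay half-time, both unitless after
# normalization to a reference construct).

#' Create a base construct
#'
#' A base construct is the reference amino-acid sequence that mutation
#' lists are expressed against (for calcium indicator libraries this is a
#' GCaMP scaffold such as GCaMP6s or jGCaMP7s).
#'
#' @param sequence Amino-acid sequence, one-letter codes, canonical 20 only.
#' @param name Construct name.
#' @param offset Construct numbering of the first residue (default 1).
#' @return An object of class `base_construct`.
#' @examples
#' base_construct("MACDEFGHIK", name = "toy")
#' @export
base_construct <- function(sequence, name = "construct", offset = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  assert_aa_string(sequence, sprintf("base construct '%s'", name))
  structure(
    list(name = name, sequence = sequence,
         length = nchar(sequence), offset = as.integer(offset)),
    class = "base_construct")
}

#' @export
print.base_construct <- function(x, ...) {
  cat(sprintf("<base_construct> %s: %d residues (numbering from %d)\n",
              x$name, x$length, x$offset))
  invisible(x)
}

#' Read a base construct from a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @param offset Construct numbering of the first residue.
#' @return A [base_construct()].
#' @export
read_base_fasta <- function(path, offset = 1L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) != 1) {
      stopf("expected a single FASTA record in '%s', found %d", path, length(set))
    }
    return(base_construct(as.character(set[[1]]),
                          name = names(set)[1], offset = offset))
  }
  # minimal fallback when Biostrings is unavailable
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) != 1) {
    stopf("expected a single FASTA record in '%s'", path)
  }
  base_construct(paste(lines[-headers], collapse = ""),
                 name = sub("^>\\s*", "", lines[headers[1]]), offset = offset)
}

#' Write a base construct as FASTA
#' @param base A [base_construct()].
#' @param path Output path.
#' @export
write_base_fasta <- function(base, path) {
  width <- 60L
  chunks <- substring(base$sequence,
                      seq(1, base$length, width),
                      pmin(seq(1, base$length, width) + width - 1L, base$length))
  writeLines(c(paste0(">", base$name), chunks), path)
  invisible(path)
}

#' Parse a mutation string
#'
#' Mutation grammar: `<RefAA><Pos><AltAA>` in construct numbering, multiple
#' substitutions joined by a delimiter (default `";"`), e.g. `"L317H;Q305D"`.
#' An empty string denotes the unmutated base.
#'
#' @param x Mutation string.
#' @param delim Delimiter between substitutions.
#' @return data.frame with columns `pos`, `ref`, `alt` (possibly 0 rows).
#' @export
parse_mutation_string <- function(x, delim = ";") {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (!nzchar(x)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  toks <- trimws(strsplit(x, delim, fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)([A-Z])$", toks))
  bad <- toks[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0) {
    stopf("unparseable mutation token(s): %s", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    pos = as.integer(vapply(m, `[`, "", 3L)),
    ref = vapply(m, `[`, "", 2L),
    alt = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE)
  if (any(!out$ref %in% AA_ALPHABET) || any(!out$alt %in% AA_ALPHABET)) {
    stopf("mutation string '%s' uses non-canonical amino-acid letters", x)
  }
  out
}

format_mutations <- function(mut, delim = ";") {
  if (nrow(mut) == 0) return("")
  paste0(mut$ref, mut$pos, mut$alt, collapse = delim)
}

#' Apply substitutions to a base construct
#'
#' @param base A [base_construct()].
#' @param mutations Either a mutation string (see [parse_mutation_string()])
#'   or a data.frame with columns `pos`, `ref`, `alt`.
#' @param delim Delimiter used when `mutations` is a string.
#' @return The mutated full-length amino-acid sequence.
#' @examples
#' apply_mutations(base_construct("ACDEF"), "D3Y")
#' @export
apply_mutations <- function(base, mutations, delim = ";") {
  stopifnot(inherits(base, "base_construct"))
  if (is.character(mutations)) mutations <- parse_mutation_string(mutations, delim)
  chars <- strsplit(base$sequence, "", fixed = TRUE)[[1]]
  if (nrow(mutations) == 0) return(base$sequence)
  idx <- mutations$pos - base$offset + 1L
  out_of_range <- idx < 1L | idx > base$length
  if (any(out_of_range)) {
    stopf("mutation position(s) out of range for %d-residue construct: %s",
          base$length, paste(mutations$pos[out_of_range], collapse = ", "))
  }
  mismatch <- chars[idx] != mutations$ref
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stopf("reference mismatch at position %d: base has %s, mutation says %s",
          mutations$pos[i], chars[idx[i]], mutations$ref[i])
  }
  chars[idx] <- mutations$alt
  paste(chars, collapse = "")
}

#' Recover the mutation list from a full sequence
#'
#' Inverse of [apply_mutations()]: diff a lifted sequence against the base.
#'
#' @param base A [base_construct()].
#' @param sequence Full-length sequence, same length as the base.
#' @return data.frame with columns `pos`, `ref`, `alt` in ascending position.
#' @export
diff_sequences <- function(base, sequence) {
  stopifnot(inherits(base, "base_construct"), nchar(sequence) == base$length)
  b <- strsplit(base$sequence, "", fixed = TRUE)[[1]]
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- which(b != s)
  data.frame(pos = idx + base$offset - 1L, ref = b[idx], alt = s[idx],
             stringsAsFactors = FALSE)
}

#' Build a variant library from a table of mutation lists
#'
#' Lifts each row's mutation string onto the base construct and collects the
#' phenotype columns. Rows missing the target phenotype are dropped with a
#' warning (they cannot enter training). The resulting library's wide
#' sequence table has `1 + L + 1` columns for one target attribute: id, one
#' column per residue, and the target value (453 columns for a 451-residue
#' scaffold).
#'
#' @param rows data.frame with columns `id`, `mutations`, and one or more
#'   phenotype columns (must include `target`).
#' @param base A [base_construct()].
#' @param target Name of the phenotype column to model.
#' @param delim Mutation-string delimiter.
#' @param source Optional source-table label; when given, ids are namespaced
#'   as `<source>:<id>` so merged datasets cannot collide.
#' @return An object of class `variant_library`.
#' @export
parse_variant_table <- function(rows, base, target, delim = ";", source = NULL) {
  stopifnot(is.data.frame(rows), inherits(base, "base_construct"))
  required <- c("id", "mutations")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    stopf("variant table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!target %in% names(rows)) {
    stopf("target attribute '%s' not found in variant table", target)
  }
  rows$id <- as.character(rows$id)
  rows$mutations <- as.character(rows$mutations)
  rows$mutations[is.na(rows$mutations)] <- ""
  if (!is.null(source)) rows$id <- paste(source, rows$id, sep = ":")
  if (anyDuplicated(rows$id)) stopf("duplicated variant ids in input table")

  seqs <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    seqs[i] <- tryCatch(
      apply_mutations(base, rows$mutations[i], delim = delim),
      error = function(e) stopf("row '%s': %s", rows$id[i], conditionMessage(e)))
  }
  phen_cols <- setdiff(names(rows), c("id", "mutations"))
  variants <- data.frame(id = rows$id, mutations = rows$mutations,
                         sequence = seqs, stringsAsFactors = FALSE)
  for (p in phen_cols) variants[[p]] <- as.numeric(rows[[p]])

  drop <- !is.finite(variants[[target]])
  if (any(drop)) {
    warning(sprintf("dropping %d record(s) missing target '%s': %s",
                    sum(drop), target,
                    paste(head(variants$id[drop], 5), collapse = ", ")),
            call. = FALSE)
    variants <- variants[!drop, , drop = FALSE]
    rownames(variants) <- NULL
  }
  new_variant_library(base, variants, target)
}

new_variant_library <- function(base, variants, target) {
  structure(list(base = base, variants = variants, target = target),
            class = "variant_library")
}

#' @export
print.variant_library <- function(x, ...) {
  cat(sprintf("<variant_library> %d variants of %s (%d aa), target '%s'\n",
              nrow(x$variants), x$base$name, x$base$length, x$target))
  invisible(x)
}

#' Number of variants in a library
#' @param lib A `variant_library`.
#' @export
n_variants <- function(lib) nrow(lib$variants)

#' Target phenotype values of a library
#' @param lib A `variant_library`.
#' @return Named numeric vector (names = variant ids).
#' @export
target_values <- function(lib) {
  setNames(lib$variants[[lib$target]], lib$variants$id)
}

#' Wide per-residue sequence table
#'
#' One row per variant: id, one column per residue (`pos<k>` in construct
#' numbering), and the target value — `1 + L + 1` columns in total.
#'
#' @param lib A `variant_library`.
#' @return data.frame with `L + 2` columns.
#' @export
sequence_table <- function(lib) {
  cm <- seq_char_matrix(lib$variants$sequence)
  colnames(cm) <- paste0("pos", seq_len(lib$base$length) + lib$base$offset - 1L)
  out <- data.frame(id = lib$variants$id, cm, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[[lib$target]] <- lib$variants[[lib$target]]
  out
}

#' Average duplicated sequences
#'
#' Variants with identical full sequences are collapsed to a single record
#' whose phenotype values are the arithmetic means of the group; the
#' surviving id is the lexicographically smallest member id. Run before
#' train/test splitting so identical sequences cannot leak across the split.
#'
#' @param lib A `variant_library`.
#' @return A deduplicated `variant_library`.
#' @export
deduplicate_average <- function(lib) {
  v <- lib$variants
  if (!anyDuplicated(v$sequence)) return(lib)
  phen_cols <- setdiff(names(v), c("id", "mutations", "sequence"))
  groups <- split(seq_len(nrow(v)), v$sequence)
  keep <- lapply(groups, function(ix) {
    sub <- v[ix, , drop = FALSE]
    rec <- sub[order(sub$id)[1], , drop = FALSE]
    for (p in phen_cols) rec[[p]] <- mean(sub[[p]])
    rec
  })
  out <- do.call(rbind, keep)
  out <- out[order(match(out$sequence, v$sequence)), , drop = FALSE]
  rownames(out) <- NULL
  new_variant_library(lib$base, out, lib$target)
}

#' Normalize phenotypes to a reference variant
#'
#' Divides every phenotype column by the reference variant's value in that
#' column, so the reference becomes exactly 1.0 (e.g. re-normalizing a
#' GCaMP3-relative library so GCaMP6s is 1.0 for all metrics).
#'
#' @param lib A `variant_library`.
#' @param reference_id Id of the reference variant.
#' @return A normalized `variant_library`.
#' @export
normalize_to_reference <- function(lib, reference_id) {
  v <- lib$variants
  i <- match(reference_id, v$id)
  if (is.na(i)) stopf("reference id '%s' not found in library", reference_id)
  phen_cols <- setdiff(names(v), c("id", "mutations", "sequence"))
  for (p in phen_cols) {
    ref <- v[[p]][i]
    if (!is.finite(ref) || ref == 0) {
      stopf("reference '%s' has zero or missing value for '%s'", reference_id, p)
    }
    v[[p]] <- v[[p]] / ref
  }
  new_variant_library(lib$base, v, lib$target)
}

#' Split a library into train and test ids
#'
#' Deterministic random partition: `floor(ratio * n)` ids go to training,
#' the remainder to test. The library should be deduplicated first so no
#' sequence appears on both sides.
#'
#' @param lib A `variant_library`.
#' @param ratio Train fraction in (0, 1); default 0.8.
#' @param seed RNG seed; default 42.
#' @return An object of class `library_split` with `train_ids`, `test_ids`,
#'   `ratio`, `seed`.
#' @export
split_train_test <- function(lib, ratio = 0.8, seed = 42L) {
  stopifnot(ratio > 0, ratio < 1)
  ids <- lib$variants$id
  n <- length(ids)
  if (n < 2) stopf("need at least 2 records to split, have %d", n)
  if (anyDuplicated(lib$variants$sequence)) {
    warning("library contains duplicated sequences; deduplicate_average() first to avoid train/test leakage",
            call. = FALSE)
  }
  n_train <- floor(ratio * n)
  perm <- withr::with_seed(seed, sample.int(n))
  structure(
    list(train_ids = ids[sort(perm[seq_len(n_train)])],
         test_ids = ids[sort(perm[seq.int(n_train + 1L, n)])],
         ratio = ratio, seed = as.integer(seed)),
    class = "library_split")
}

#' @export
print.library_split <- function(x, ...) {
  cat(sprintf("<library_split> %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$ratio, x$seed))
  invisible(x)
}

#' Subset a library by variant ids
#' @param lib A `variant_library`.
#' @param ids Character vector of ids to keep (order preserved).
#' @export
subset_library <- function(lib, ids) {
  i <- match(ids, lib$variants$id)
  if (anyNA(i)) stopf("unknown id(s): %s", paste(ids[is.na(i)], collapse = ", "))
  v <- lib$variants[i, , drop = FALSE]
  rownames(v) <- NULL
  new_variant_library(lib$base, v, lib$target)
}

#' Read / write variant library CSV
#'
#' The on-disk dialect is `id,mutations,<phenotype columns>`; sequences are
#' re-lifted from the mutation strings on read.
#'
#' @param path CSV path.
#' @param base A [base_construct()].
#' @param target Target phenotype column name.
#' @param delim Mutation-string delimiter.
#' @rdname variant_csv
#' @export
read_variant_csv <- function(path, base, target, delim = ";") {
  rows <- read.csv(path, stringsAsFactors = FALSE)
  parse_variant_table(rows, base, target, delim = delim)
}

#' @param lib A `variant_library`.
#' @rdname variant_csv
#' @export
write_variant_csv <- function(lib, path) {
  out <- lib$variants[, setdiff(names(lib$variants), "sequence"), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a split manifest as JSON
#' @param split A `library_split`.
#' @param path JSON path.
#' @rdname split_json
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname split_json
#' @export
read_split_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 ratio = x$ratio, seed = as.integer(x$seed)),
            class = "library_split")
}
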