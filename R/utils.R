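# shared internal helpers

#' @useDynLib varsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans prcomp predict pt sd var runif rnorm setNames
#' @importFrom stats lm coef nls cor rbinom
#' @importFrom utils read.csv write.csv head modifyList
NULL

# canonical one-letter amino-acid alphabet, alphabetical (fixed column order
# for one-hot encoding and label codes)
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
AA_ALPHABET <- sort(AA_ALPHABET)

# AAINDEX flat files list values in this residue order (two rows of ten)
AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_aa_string <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stopf("%s contains non-canonical amino-acid letters: %s",
          what, paste(bad, collapse = ", "))
  }
  invisible(chars)
}

# split sequences into an n x L character matrix
seq_char_matrix <- function(sequences) {
  if (length(sequences) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  L <- nchar(sequences[1])
  if (any(nchar(sequences) != L)) {
    stopf("sequences have unequal lengths")
  }
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}
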