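# Scoring alphabets for template matching.

# BLOSUM62, 20 standard residues, standard published ordering.
BLOSUM62_20 <- local({
  m <- matrix(c(
      4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
     -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
     -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
     -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
      0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
     -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
     -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
      0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
     -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
     -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
     -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
     -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
     -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
     -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
     -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
      1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
      0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
     -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
     -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
      0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4),
    nrow = 20, byrow = TRUE, dimnames = list(AA20, AA20))
  m
})

#' Construct a scoring alphabet
#'
#' A scoring alphabet bundles the residue symbols, a symmetric integer
#' substitution matrix and affine gap penalties used for all alignments
#' (template matching, junction scoring and homology distances).
#'
#' @param matrix symmetric numeric substitution matrix with identical row and
#'   column names (the symbol set).
#' @param gap_open nonnegative penalty charged for the first residue of a
#'   gap run.
#' @param gap_extend nonnegative penalty for each further gap residue.
#' @return an object of class `scoring_alphabet`.
#' @export
scoring_alphabet <- function(matrix, gap_open = 12, gap_extend = 1) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    validation_error("substitution matrix must have identical row/column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    validation_error("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0)
    validation_error("gap penalties must be nonnegative")
  structure(list(symbols = rownames(matrix),
                 matrix = matrix,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_alphabet")
}

#' Default mass-spectrometry-aware scoring alphabet
#'
#' BLOSUM62 over the 20 standard residues plus the wildcard `X`, with
#' overrides reflecting what a mass spectrometer can and cannot see:
#' isoleucine and leucine are isobaric and indistinguishable in standard
#' fragmentation, so they form a single residue class --
#' `score(I, L) = score(I, I) = score(L, L) = 4` and, against every other
#' residue, I and L both take the more favorable of their two BLOSUM62
#' scores (so alignment scores are invariant to the arbitrary I/L choice a
#' de novo engine makes). `X` (used for junction extension placeholders)
#' scores 0 against everything. Affine gaps: open 12, extend 1.
#'
#' @return a `scoring_alphabet`.
#' @examples
#' ab <- default_alphabet()
#' ab$matrix["I", "L"]  # 4: I/L are mass-identical
#' ab$matrix["X", "W"]  # 0: wildcard
#' @export
default_alphabet <- function() {
  syms <- c(AA20, "X")
  m <- matrix(0, 21, 21, dimnames = list(syms, syms))
  m[AA20, AA20] <- BLOSUM62_20
  m["I", "L"] <- m["L", "I"] <- m["I", "I"] <- m["L", "L"] <- 4
  for (x in setdiff(AA20, c("I", "L"))) {
    v <- max(m["I", x], m["L", x])
    m["I", x] <- m[x, "I"] <- v
    m["L", x] <- m[x, "L"] <- v
  }
  m["X", ] <- 0
  m[, "X"] <- 0
  scoring_alphabet(m, gap_open = 12, gap_extend = 1)
}

#' Read a scoring alphabet from a TSV matrix file
#'
#' The file holds a square matrix: a header row of symbols, then one row per
#' symbol with the symbol in the first column. Gap penalties are supplied as
#' arguments (they are run parameters, not part of the matrix).
#'
#' @param path path to the TSV file.
#' @inheritParams scoring_alphabet
#' @return a `scoring_alphabet`.
#' @export
read_alphabet_tsv <- function(path, gap_open = 12, gap_extend = 1) {
  if (!file.exists(path)) format_error("alphabet file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    format_error("alphabet matrix is not square: ", path)
  scoring_alphabet(m, gap_open, gap_extend)
}

#' @export
print.scoring_alphabet <- function(x, ...) {
  cat("Scoring alphabet:", length(x$symbols), "symbols (",
      paste(utils::head(x$symbols, 6), collapse = ""), "...);",
      "gap open", x$gap_open, "/ extend", x$gap_extend, "\n")
  invisible(x)
}

# Encode a sequence as 0-based indices into the alphabet matrix.
encode_seq <- function(seq, alphabet) {
  cc <- chars(seq)
  idx <- match(cc, alphabet$symbols)
  if (anyNA(idx)) {
    bad <- cc[which(is.na(idx))[1]]
    validation_error("symbol '", bad, "' not in the scoring alphabet")
  }
  idx - 1L
}
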