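#' Map DNA words to mCGR grid coordinates and back
#'
#' Every DNA word of length n corresponds to exactly one cell of the
#' 2^n x 2^n mCGR grid. Character i of the word (counted from the start)
#' contributes bit i - 1 of the row and column numbers, so the first
#' character sets the finest bits and the last character the coarsest: all
#' words in one quadrant of the grid share their final letter, and the grid
#' is self-similar under the doubling recursion.
#'
#' `seqToCoord()` returns the 0-based (row, col) coordinates of one or more
#' equal-length words; `coordToSeq()` is its exact inverse
#' (back-calculation), recovering the word from a cell position.
#'
#' @param seq character vector (or [Biostrings::DNAStringSet]) of DNA words,
#'   all of the same length, alphabet {A,C,G,T}.
#' @param row,col numeric vectors of 0-based coordinates in [0, 2^order).
#' @param order word length n.
#' @param layout a [NucleotideLayout-class]; default \code{[[A,T],[G,C]]}.
#' @return `seqToCoord()`: a data.frame with columns `row`, `col` and
#'   attribute-free `order` column; `coordToSeq()`: a character vector of
#'   words.
#' @examples
#' seqToCoord("CC")            # row 3, col 3
#' seqToCoord("AT")            # row 0, col 2
#' coordToSeq(3, 3, 2)         # "CC"
#' coordToSeq(0, 1, 2)         # "TA"
#' @export
seqToCoord <- function(seq, layout = layoutATGC()) {
  seq <- toupper(as.character(seq))
  if (!length(seq)) stop("'seq' must be non-empty")
  n <- unique(nchar(seq))
  if (length(n) != 1L || n < 1L)
    stop("all sequences must be non-empty and of equal length")
  .checkAlphabet(seq)
  bits <- .layoutBits(layout)
  row <- col <- numeric(length(seq))
  for (i in seq_len(n)) {
    ch <- substr(seq, i, i)
    rb <- vapply(bits, `[`, numeric(1), 1L)[ch]
    cb <- vapply(bits, `[`, numeric(1), 2L)[ch]
    w <- 2^(i - 1)
    row <- row + rb * w
    col <- col + cb * w
  }
  data.frame(row = unname(row), col = unname(col), order = n)
}

#' @rdname seqToCoord
#' @export
coordToSeq <- function(row, col, order, layout = layoutATGC()) {
  order <- as.integer(order)
  if (length(order) != 1L || order < 1L)
    stop("'order' must be a single positive integer")
  lim <- 2^order
  if (any(row < 0 | row >= lim) || any(col < 0 | col >= lim))
    stop(sprintf("coordinates out of range [0, 2^%d)", order))
  if (any(row != floor(row)) || any(col != floor(col)))
    stop("coordinates must be integers")
  letters4 <- .layoutQuadrantLetters(layout)
  parts <- vector("list", order)
  for (i in seq_len(order)) {
    rb <- row %% 2; cb <- col %% 2
    parts[[i]] <- letters4[2 * rb + cb + 1]
    row <- row %/% 2; col <- col %/% 2
  }
  do.call(paste0, parts)
}

## word index k = row * 2^n + col, the canonical linearisation used by the
## pairwise Hamming table and the dense exports
.coordIndex <- function(row, col, order) row * 2^order + col

.indexCoord <- function(k, order) {
  lim <- 2^order
  list(row = k %/% lim, col = k %% lim)
}
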