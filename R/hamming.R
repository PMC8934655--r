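#' Single-nucleotide Hamming generator
#'
#' The 2 x 2 generator for Hamming distances: 0 at the given nucleotide's
#' layout quadrant and 1 everywhere else, i.e. the distance of every
#' single-letter word to that nucleotide.
#'
#' @param nucleotide one of A, C, G, T.
#' @param layout a [NucleotideLayout-class].
#' @return a 2 x 2 integer matrix.
#' @examples
#' b1Matrix("A")  # [[0,1],[1,1]]
#' b1Matrix("C")  # [[1,1],[1,0]]
#' @export
b1Matrix <- function(nucleotide, layout = layoutATGC()) {
  nucleotide <- toupper(nucleotide)
  if (length(nucleotide) != 1L || !nucleotide %in% .DNA_LETTERS)
    stop("'nucleotide' must be one of A, C, G, T")
  b <- matrix(1L, 2, 2)
  b[layout@letters == nucleotide] <- 0L
  b
}

#' Hamming distances from one word to all words
#'
#' Builds the 2^n x 2^n grid of Hamming distances between a reference word s
#' and every word of the same length, by appending one generator per
#' character:
#' \deqn{H(s)^n = 1^2 \otimes H(s)^{n-1} + B^1(s_n) \otimes 1^{2^{n-1}}}
#' with H(s)^1 = B^1(s_1) from [b1Matrix()]. The cell at coordinate (r, q)
#' equals the Hamming distance between s and the word at (r, q).
#'
#' @param s the reference DNA word (default cap 10 characters).
#' @param layout a [NucleotideLayout-class].
#' @param override set TRUE to lift the cap.
#' @return a [HammingMatrix-class].
#' @examples
#' as.matrix(hammingToWord("A"))
#' @export
hammingToWord <- function(s, layout = layoutATGC(), override = FALSE) {
  s <- toupper(as.character(s))
  if (length(s) != 1L || !nzchar(s)) stop("'s' must be one non-empty DNA string")
  .checkAlphabet(s)
  n <- nchar(s)
  .checkOrderCap(n, cap = 10L, override = override)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  H <- b1Matrix(chars[1], layout)
  if (n > 1L) {
    for (k in 2:n)
      H <- kronecker(matrix(1L, 2, 2), H) +
           kronecker(b1Matrix(chars[k], layout), matrix(1L, 2^(k - 1), 2^(k - 1)))
  }
  storage.mode(H) <- "integer"
  new("HammingMatrix", order = n, reference = s, values = H, layout = layout)
}

#' Full pairwise Hamming table
#'
#' Builds the dense 4^n x 4^n table of Hamming distances between all pairs of
#' DNA words of length n, by the same doubling recursion with the 4 x 4
#' all-ones-minus-identity generator (distance of one letter to each letter):
#' \deqn{T^n = 1^4 \otimes T^{n-1} + T^1 \otimes 1^{4^{n-1}}}
#' The natural index of that recursion orders words by per-character base-4
#' digits; the result is then permuted so that word w with mCGR coordinate
#' (r, q) sits at index k = r 2^n + q, consistent with the flattening of
#' [hammingToWord()] grids.
#'
#' @param n word length (cap 6: the table is dense).
#' @param layout a [NucleotideLayout-class].
#' @param override set TRUE to lift the cap.
#' @return a [PairwiseTable-class].
#' @examples
#' as.matrix(pairwiseTable(1))  # 4 x 4, ones minus identity
#' @export
pairwiseTable <- function(n, layout = layoutATGC(), override = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  .checkOrderCap(n, cap = 6L, override = override)
  T1 <- matrix(1L, 4, 4) - diag(1L, 4)
  Tn <- T1
  if (n > 1L) {
    for (k in 2:n)
      Tn <- kronecker(matrix(1L, 4, 4), Tn) +
            kronecker(T1, matrix(1L, 4^(k - 1), 4^(k - 1)))
  }
  ## permute digit-order indices to k = row * 2^n + col order
  p <- .digitIndexOf(0:(4^n - 1), n) + 1
  Tn <- Tn[p, p]
  storage.mode(Tn) <- "integer"
  new("PairwiseTable", wordLength = n, values = Tn, layout = layout)
}

## base-4 digit index (char i -> digit 2*rowbit_i + colbit_i, weight 4^(i-1))
## of the word whose mCGR linear index is k = row * 2^n + col
.digitIndexOf <- function(k, n) {
  rc <- .indexCoord(k, n)
  row <- rc$row; col <- rc$col
  j <- numeric(length(k))
  for (i in seq_len(n)) {
    d <- 2 * (row %% 2) + col %% 2
    j <- j + d * 4^(i - 1)
    row <- row %/% 2; col <- col %/% 2
  }
  j
}
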