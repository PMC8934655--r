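#' @import methods
#' @importFrom stats setNames
NULL

.DNA_LETTERS <- c("A", "C", "G", "T")

#' NucleotideLayout: corner assignment of the mCGR grid
#'
#' Assigns each nucleotide to one quadrant of the chaos-game square, i.e. to a
#' (row bit, column bit) pair. The layout fixes which fractal patterns emerge
#' (e.g. GC stripes versus flower-like patterns) but never changes which words
#' a constraint admits.
#'
#' @slot letters 2 x 2 character matrix; \code{letters[r + 1, c + 1]} is the
#'   nucleotide whose row bit is \code{r} and column bit is \code{c}.
#'
#' @seealso [nucleotideLayout()], [layoutATGC()], [layoutACGT()]
#' @export
setClass("NucleotideLayout", representation(letters = "matrix"))

setValidity("NucleotideLayout", function(object) {
  l <- object@letters
  if (!is.character(l) || !identical(dim(l), c(2L, 2L)))
    return("'letters' must be a 2 x 2 character matrix")
  if (!setequal(as.vector(l), .DNA_LETTERS))
    return("'letters' must be a bijection onto {A,C,G,T}")
  TRUE
})

#' ConstraintMatrix: sparse mCGR of constraint violations
#'
#' The 2^n x 2^n matrix chaos game representation (mCGR) whose cell (row, col)
#' corresponds bijectively to one DNA word of length n. Only violating cells
#' are stored (position triplets); the value at a stored cell counts the
#' (possibly overlapping) occurrences of the forbidden word(s) in the DNA word
#' at that cell, and an absent cell means zero occurrences, i.e. an allowed
#' word.
#'
#' @slot order matrix order n (word length).
#' @slot row,col 0-based coordinates of flagged cells, each in [0, 2^n).
#' @slot count occurrence counts, all >= 1.
#'
#' @seealso [motifMatrix()], [extendConstraint()], [addMatrices()]
#' @export
setClass("ConstraintMatrix",
  representation(order = "integer", row = "numeric", col = "numeric",
                 count = "numeric"))

setValidity("ConstraintMatrix", function(object) {
  n <- object@order
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("'order' must be a single positive integer")
  m <- length(object@row)
  if (length(object@col) != m || length(object@count) != m)
    return("'row', 'col' and 'count' must have equal length")
  lim <- 2^n
  if (m) {
    if (any(object@row < 0) || any(object@row >= lim) ||
        any(object@col < 0) || any(object@col >= lim))
      return(sprintf("coordinates must lie in [0, 2^%d)", n))
    if (any(object@count < 1))
      return("stored counts must all be >= 1")
    if (anyDuplicated(object@row * lim + object@col))
      return("duplicate coordinates")
  }
  TRUE
})

#' GcMatrix: per-word GC counts on the mCGR grid
#'
#' Dense 2^n x 2^n integer matrix whose cell holds the number of G/C
#' characters of the word at that cell, built by the doubling recursion
#' D^n = 1 (x) D^1 + D^(n-1) (x) 1 from the layout's 2 x 2 generator.
#'
#' @slot order word length n.
#' @slot values 2^n x 2^n integer matrix; \code{values[r + 1, q + 1]} is the
#'   GC count of the word at 0-based coordinate (r, q).
#' @slot layout the [NucleotideLayout-class] used.
#'
#' @seealso [gcCountMatrix()]
#' @export
setClass("GcMatrix",
  representation(order = "integer", values = "matrix",
                 layout = "NucleotideLayout"))

setValidity("GcMatrix", function(object) {
  d <- 2^object@order
  if (!identical(dim(object@values), c(as.integer(d), as.integer(d))))
    return("'values' must be 2^order x 2^order")
  if (any(object@values < 0) || any(object@values > object@order))
    return("GC counts must lie in [0, order]")
  TRUE
})

#' HammingMatrix: distances from one word to all words
#'
#' Dense 2^n x 2^n matrix of Hamming distances from a fixed reference word to
#' every word of the same length, arranged on the mCGR grid.
#'
#' @slot order word length n.
#' @slot reference the reference word.
#' @slot values 2^n x 2^n integer matrix of distances in [0, n].
#' @slot layout the [NucleotideLayout-class] used.
#'
#' @seealso [hammingToWord()]
#' @export
setClass("HammingMatrix",
  representation(order = "integer", reference = "character",
                 values = "matrix", layout = "NucleotideLayout"))

setValidity("HammingMatrix", function(object) {
  d <- 2^object@order
  if (!identical(dim(object@values), c(as.integer(d), as.integer(d))))
    return("'values' must be 2^order x 2^order")
  if (nchar(object@reference) != object@order)
    return("reference word length must equal 'order'")
  if (any(object@values < 0) || any(object@values > object@order))
    return("distances must lie in [0, order]")
  TRUE
})

#' PairwiseTable: all-against-all Hamming distances
#'
#' Dense 4^n x 4^n table of pairwise Hamming distances between all DNA words
#' of length n. Word w with mCGR coordinate (r, q) is indexed by
#' k = r * 2^n + q (0-based), so rows/columns align with the flattened
#' [HammingMatrix-class] of the corresponding word.
#'
#' @slot wordLength word length n.
#' @slot values 4^n x 4^n integer matrix.
#' @slot layout the [NucleotideLayout-class] used for the word indexing.
#'
#' @seealso [pairwiseTable()]
#' @export
setClass("PairwiseTable",
  representation(wordLength = "integer", values = "matrix",
                 layout = "NucleotideLayout"))

setValidity("PairwiseTable", function(object) {
  d <- 4^object@wordLength
  if (!identical(dim(object@values), c(as.integer(d), as.integer(d))))
    return("'values' must be 4^wordLength x 4^wordLength")
  TRUE
})

#' ConstraintSpec: user constraints for a codebook
#'
#' Bundles the constraints a codebook must satisfy: word length, an inclusive
#' GC-content interval (unset bounds are unconstrained), a maximum homopolymer
#' run length, and a set of forbidden motifs. A fixed ("strong") GC content is
#' expressed by setting \code{gcMin == gcMax}.
#'
#' @slot wordLength code word length n (positive integer).
#' @slot gcMin,gcMax GC fraction bounds in [0, 1], or NA for unconstrained.
#' @slot maxHomopolymer maximum allowed run of identical nucleotides, or NA.
#' @slot motifs character vector of forbidden motifs (each of length <= n).
#' @slot layout the [NucleotideLayout-class].
#'
#' @seealso [constraintSpec()], [buildCodebook()]
#' @export
setClass("ConstraintSpec",
  representation(wordLength = "integer", gcMin = "numeric", gcMax = "numeric",
                 maxHomopolymer = "integer", motifs = "character",
                 layout = "NucleotideLayout"))

setValidity("ConstraintSpec", function(object) {
  n <- object@wordLength
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("'wordLength' must be a single positive integer")
  gmin <- object@gcMin; gmax <- object@gcMax
  for (g in c(gmin, gmax))
    if (!is.na(g) && (g < 0 || g > 1))
      return("GC bounds must lie in [0, 1]")
  if (!is.na(gmin) && !is.na(gmax) && gmin > gmax)
    return("'gcMin' must not exceed 'gcMax'")
  if (!is.na(object@maxHomopolymer) && object@maxHomopolymer < 1L)
    return("'maxHomopolymer' must be >= 1")
  if (length(object@motifs)) {
    if (any(grepl("[^ACGT]", object@motifs)))
      return("motifs must use the alphabet {A,C,G,T}")
    if (any(nchar(object@motifs) > n))
      return("all motifs must be no longer than 'wordLength'")
    if (any(nchar(object@motifs) < 1L))
      return("empty motif")
  }
  TRUE
})

#' Codebook: a set of allowed code words
#'
#' A lexicographically sorted (A < C < G < T) set of distinct DNA words of one
#' fixed length, together with the [ConstraintSpec-class] that produced it and
#' a flag recording whether concatenation-safe pruning has been applied.
#'
#' @slot wordLength word length n.
#' @slot words sorted character vector of code words.
#' @slot spec the producing [ConstraintSpec-class], or NULL for codebooks read
#'   from FASTA without provenance.
#' @slot concatSafe TRUE after [concatSafeFilter()].
#'
#' @seealso [buildCodebook()], [readCodebook()], [codeRate()]
#' @export
setClass("Codebook",
  representation(wordLength = "integer", words = "character",
                 spec = "ANY", concatSafe = "logical"))

setValidity("Codebook", function(object) {
  w <- object@words
  if (length(w)) {
    if (any(nchar(w) != object@wordLength))
      return("all words must have length 'wordLength'")
    if (any(grepl("[^ACGT]", w)))
      return("words must use the alphabet {A,C,G,T}")
    if (is.unsorted(w, strictly = TRUE))
      return("words must be strictly sorted (A < C < G < T)")
  }
  if (!is.null(object@spec) && !is(object@spec, "ConstraintSpec"))
    return("'spec' must be a ConstraintSpec or NULL")
  TRUE
})
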