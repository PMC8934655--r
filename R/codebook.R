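.newCodebook <- function(words, wordLength, spec = NULL, concatSafe = FALSE) {
  new("Codebook", wordLength = as.integer(wordLength),
      words = words, spec = spec, concatSafe = concatSafe)
}

#' Construct a codebook from explicit words
#'
#' Builds a [Codebook-class] directly from a set of equal-length DNA words,
#' case-folding, deduplicating and sorting them lexicographically
#' (A < C < G < T). Mostly useful for small worked examples; [buildCodebook()]
#' is the constraint-driven constructor.
#'
#' @param words character vector of DNA words of one common length.
#' @param spec optional [ConstraintSpec-class] provenance.
#' @return a [Codebook-class].
#' @examples
#' codebook(c("A", "C", "G", "T"))
#' @export
codebook <- function(words, spec = NULL) {
  words <- toupper(as.character(words))
  if (!length(words)) stop("'words' must be non-empty")
  lens <- unique(nchar(words))
  if (length(lens) != 1L) stop("all words must have the same length")
  .checkAlphabet(words, "word")
  .newCodebook(sort(unique(words), method = "radix"), lens, spec)
}

#' Build the codebook of all words satisfying a constraint specification
#'
#' Assembles the combined forbidden-substring matrix (the sum of
#' [motifMatrix()] over the spec's motifs and the homopolymer-derived
#' motifs), enumerates all 4^n grid cells, keeps those with violation count
#' zero and an admissible GC count (from [gcCountMatrix()]), back-calculates
#' the cell coordinates to sequences and sorts them lexicographically
#' (A < C < G < T).
#'
#' A contradictory specification yields an empty codebook with a warning, not
#' an error. The full enumeration is capped at n = 12 by default.
#'
#' @param spec a [ConstraintSpec-class].
#' @param override set TRUE to lift the enumeration cap.
#' @return a [Codebook-class].
#' @examples
#' length(buildCodebook(constraintSpec(2, maxHomopolymer = 1)))  # 12
#' length(buildCodebook(constraintSpec(3, motifs = "CC")))       # 57
#' @export
buildCodebook <- function(spec, override = FALSE) {
  stopifnot(is(spec, "ConstraintSpec"))
  n <- spec@wordLength
  .checkOrderCap(n, cap = 12L, override = override)
  layout <- spec@layout
  motifs <- .effectiveMotifs(spec)
  if (any(nchar(motifs) > n))
    stop("all motifs (and homopolymer runs + 1) must fit into 'wordLength'")

  allowed <- rep(TRUE, 4^n)
  if (length(motifs)) {
    forb <- Reduce(addMatrices,
                   lapply(motifs, motifMatrix, n = n, layout = layout,
                          override = override))
    allowed <- .violationVector(forb) == 0
  }
  if (!is.na(spec@gcMin) || !is.na(spec@gcMax)) {
    gcm <- gcCountMatrix(n, layout, override = override)
    ## cell (r, q) -> linear index k = r * 2^n + q: row-major flattening
    gcByIndex <- as.vector(t(gcm@values))
    allowed <- allowed & gcAllowed(gcByIndex, n, spec@gcMin, spec@gcMax)
  }
  k <- which(allowed) - 1
  if (!length(k)) {
    warning("constraint specification admits no words: empty codebook")
    return(.newCodebook(character(0), n, spec))
  }
  rc <- .indexCoord(k, n)
  words <- coordToSeq(rc$row, rc$col, n, layout)
  .newCodebook(sort(words, method = "radix"), n, spec)
}

#' Concatenation-safe pruning
#'
#' Removes every word that could take part in building a forbidden motif
#' across the junction of two concatenated words. A junction occurrence of a
#' motif m of length L splits into a suffix piece of k1 leading motif
#' letters at the end of the first word and the complementary prefix piece
#' of L - k1 trailing motif letters at the start of the second. The filter
#' drops words whose length-k suffix equals the first k letters of m for any
#' k >= ceil(L/2), and words whose length-k prefix equals the last k letters
#' of m for any k >= L + 1 - ceil(L/2). Every possible split then triggers
#' at least one of the two removals (k1 >= ceil(L/2) hits the suffix rule,
#' otherwise L - k1 >= L + 1 - ceil(L/2) hits the prefix rule), so surviving
#' words concatenate freely in any order without creating a motif occurrence
#' spanning a boundary - and the thresholds are complementary, so no word is
#' dropped that a junction could never implicate. For an odd-length motif
#' the two thresholds coincide at (L+1)/2: for the homopolymer AAA exactly
#' the words ending with AA and the words starting with AA are removed.
#'
#' @param book a [Codebook-class].
#' @param motifs forbidden motifs to protect junctions against; defaults to
#'   the book's own spec motifs plus its homopolymer runs.
#' @return the pruned [Codebook-class], flagged concatenation-safe.
#' @export
concatSafeFilter <- function(book, motifs = NULL) {
  stopifnot(is(book, "Codebook"))
  if (is.null(motifs)) {
    if (is.null(book@spec))
      stop("'book' has no spec; supply 'motifs' explicitly")
    motifs <- .effectiveMotifs(book@spec)
  }
  motifs <- unique(toupper(motifs))
  if (length(motifs)) .checkAlphabet(motifs, "motif")
  n <- book@wordLength
  words <- book@words
  if (any(nchar(motifs) > n))
    stop("motifs longer than the word length cannot be junction-checked")
  keep <- rep(TRUE, length(words))
  for (m in motifs) {
    L <- nchar(m)
    if (L < 2L) next          # a 1-letter motif cannot span a junction
    kSuffix <- ceiling(L / 2)         # word ends with >= this much motif start
    kPrefix <- L + 1L - kSuffix       # word starts with >= this much motif end
    for (k in seq.int(kSuffix, L - 1L))
      keep <- keep & substr(words, n - k + 1L, n) != substr(m, 1L, k)
    if (kPrefix <= L - 1L)
      for (k in seq.int(kPrefix, L - 1L))
        keep <- keep & substr(words, 1L, k) != substr(m, L - k + 1L, L)
  }
  .newCodebook(words[keep], n, book@spec, concatSafe = TRUE)
}

#' Code rate of a codebook
#'
#' Information carried per nucleotide, log2(|C|)/n bits/nt; at most 2 (the
#' unconstrained codebook of all 4^n words).
#'
#' @param x a [Codebook-class] (or an integer codebook size, with `n` given).
#' @return code rate in bits per nucleotide.
#' @examples
#' codeRate(buildCodebook(constraintSpec(2, maxHomopolymer = 1)))
#' @rdname codeRate
#' @export
setMethod("codeRate", "Codebook", function(x) {
  if (!length(x@words)) stop("code rate is undefined for an empty codebook")
  log2(length(x@words)) / x@wordLength
})

#' @param n word length, when `x` is a plain codebook size.
#' @rdname codeRate
#' @export
setMethod("codeRate", "numeric", function(x, n) {
  if (x < 1) stop("code rate is undefined for an empty codebook")
  log2(x) / n
})

#' Codebook FASTA input and output
#'
#' Codebooks are exchanged as plain FASTA, one word per record with
#' sequential ids `w000001`, `w000002`, ... `readCodebook()` validates the
#' uniform word length and strict alphabet, and sorts unsorted files with a
#' message; `writeCodebook()` then `readCodebook()` is the identity.
#'
#' @param book a [Codebook-class].
#' @param path file path.
#' @return `readCodebook()`: a [Codebook-class] (without provenance spec).
#' @export
writeCodebook <- function(book, path) {
  stopifnot(is(book, "Codebook"))
  set <- Biostrings::DNAStringSet(book@words)
  names(set) <- sprintf("w%06d", seq_along(book@words))
  Biostrings::writeXStringSet(set, path, width = max(80L, book@wordLength))
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  words <- toupper(as.character(set))
  if (!length(words)) stop("empty codebook file")
  lens <- unique(nchar(words))
  if (length(lens) != 1L)
    stop("mixed word lengths in codebook file: ", paste(lens, collapse = ", "))
  if (any(grepl("[^ACGT]", words)))
    stop("codebook contains characters outside {A,C,G,T}")
  words <- unname(words)
  sorted <- sort(words, method = "radix")
  if (!identical(words, sorted))
    message("codebook file was not sorted; sorting lexicographically")
  if (anyDuplicated(sorted)) stop("duplicate words in codebook file")
  .newCodebook(sorted, lens)
}
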