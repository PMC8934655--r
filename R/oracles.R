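## Independent brute-force references. Everything here works on plain
## strings (substring scans), sharing no machinery with the matrix
## recursions, so agreement between the two routes is meaningful evidence.

#' Enumerate all DNA words of a given length
#'
#' All 4^n words in lexicographic order (A < C < G < T). Guarded at n <= 8:
#' this is reference/oracle machinery, not the production enumeration.
#'
#' @param n word length, n <= 8.
#' @return character vector of 4^n words.
#' @export
allWords <- function(n) {
  n <- as.integer(n)
  if (n < 1L || n > 8L) stop("'n' must be in 1..8 (oracle guard)")
  g <- expand.grid(rep(list(.DNA_LETTERS), n), stringsAsFactors = FALSE)
  ## expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, rev(g)), method = "radix")
}

#' Brute-force overlapping occurrence count
#'
#' Counts occurrences (including overlapping ones) of each motif in each
#' word by a positional substring scan, summed over motifs. This is the
#' string-space oracle for the counts stored in a [ConstraintMatrix-class].
#'
#' @param words character vector of DNA words.
#' @param motifs character vector of motifs.
#' @return integer vector of summed occurrence counts, one per word.
#' @examples
#' bruteForceOccurrences("CCC", "CC")   # 2
#' bruteForceOccurrences("ACGT", "CC")  # 0
#' @export
bruteForceOccurrences <- function(words, motifs) {
  total <- integer(length(words))
  n <- nchar(words)
  for (m in motifs) {
    L <- nchar(m)
    maxStart <- max(n) - L + 1L
    if (maxStart < 1L) next
    for (p in seq_len(maxStart))
      total <- total + (substr(words, p, p + L - 1L) == m)
  }
  total
}

#' Brute-force codebook enumeration
#'
#' String-filter reference for [buildCodebook()]: enumerates all 4^n words
#' and keeps those with no motif occurrence (substring scan), homopolymer
#' runs within the limit (regular-expression scan) and GC fraction within
#' the inclusive bounds. Guarded at n <= 8.
#'
#' @param spec a [ConstraintSpec-class] with wordLength <= 8.
#' @return sorted character vector of allowed words.
#' @export
bruteForceCodebook <- function(spec) {
  stopifnot(is(spec, "ConstraintSpec"))
  n <- spec@wordLength
  if (n > 8L) stop("'wordLength' must be <= 8 (oracle guard)")
  words <- allWords(n)
  keep <- rep(TRUE, length(words))
  for (m in spec@motifs)
    keep <- keep & !grepl(m, words, fixed = TRUE)
  if (!is.na(spec@maxHomopolymer)) {
    r <- spec@maxHomopolymer + 1L
    pat <- paste(sprintf("%s{%d}", .DNA_LETTERS, r), collapse = "|")
    keep <- keep & !grepl(pat, words)
  }
  gc <- nchar(gsub("[AT]", "", words)) / n
  eps <- 1e-9
  if (!is.na(spec@gcMin)) keep <- keep & gc >= spec@gcMin - eps
  if (!is.na(spec@gcMax)) keep <- keep & gc <= spec@gcMax + eps
  words[keep]
}

#' Seeded random constraint specifications
#'
#' Draws reproducible random [ConstraintSpec-class]s for property testing:
#' GC bounds from {unconstrained, [0.4, 0.6], exactly 0.5}, maximum
#' homopolymer run from {1, 2, 3, unconstrained} and 0-3 random motifs of
#' length 2-4.
#'
#' @param count number of specs.
#' @param seed RNG seed.
#' @param wordLengths word lengths to sample from.
#' @return list of [ConstraintSpec-class] objects.
#' @export
randomConstraintSpecs <- function(count, seed, wordLengths = 4:8) {
  set.seed(seed)
  lapply(seq_len(count), function(i) {
    n <- sample(wordLengths, 1L)
    gcChoice <- sample(3L, 1L)
    gmin <- c(NA, 0.4, 0.5)[gcChoice]
    gmax <- c(NA, 0.6, 0.5)[gcChoice]
    hp <- sample(list(1L, 2L, 3L, NA_integer_), 1L)[[1]]
    nm <- sample(0:3, 1L)
    motifs <- vapply(seq_len(nm), function(j) {
      paste(sample(.DNA_LETTERS, sample(2:4, 1L), replace = TRUE),
            collapse = "")
    }, character(1))
    constraintSpec(n, gcMin = gmin, gcMax = gmax, maxHomopolymer = hp,
                   motifs = motifs)
  })
}

#' Write a deterministic fixture set
#'
#' Generates, purely from the seed, a small motif FASTA, a constrained
#' codebook FASTA and random binary payload blobs (stand-ins for an image
#' corpus: content is irrelevant to a lossless codec) under `dir`. The same
#' seed reproduces byte-identical files.
#'
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @param payloadSizes payload blob sizes in bytes.
#' @param wordLength word length of the generated codebook.
#' @return named list of the file paths written.
#' @export
makeFixtures <- function(dir, seed = 1L,
                         payloadSizes = c(2048L, 16384L, 65536L),
                         wordLength = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  motifs <- vapply(1:3, function(i) {
    paste(sample(.DNA_LETTERS, sample(3:5, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
  motifPath <- file.path(dir, "motifs.fasta")
  set <- Biostrings::DNAStringSet(motifs)
  names(set) <- sprintf("m%02d", seq_along(motifs))
  Biostrings::writeXStringSet(set, motifPath)

  spec <- constraintSpec(wordLength, gcMin = 0.4, gcMax = 0.6,
                         maxHomopolymer = 3L)
  book <- concatSafeFilter(buildCodebook(spec))
  bookPath <- file.path(dir, "codebook.fasta")
  writeCodebook(book, bookPath)

  payloadPaths <- vapply(seq_along(payloadSizes), function(i) {
    p <- file.path(dir, sprintf("payload_%02d.bin", i))
    writeBin(as.raw(sample(0:255, payloadSizes[i], replace = TRUE)), p)
    p
  }, character(1))

  list(motifs = motifPath, codebook = bookPath, payloads = payloadPaths)
}
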