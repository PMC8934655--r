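# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

# The length-10 reference codebook: GC 40-60%, homopolymer runs <= 3,
# no extra motifs, concatenation-safe. Building it enumerates all 4^10
# words, so it is memoised across test files.
storageCodebook <- function() {
  if (is.null(.cache$book10)) {
    spec <- constraintSpec(10, gcMin = 0.4, gcMax = 0.6, maxHomopolymer = 3)
    .cache$book10 <- concatSafeFilter(buildCodebook(spec))
  }
  .cache$book10
}

# all 4^n words in k = row*2^n + col order, via the back-calculation
wordsInGridOrder <- function(n, layout = layoutATGC()) {
  k <- 0:(4^n - 1)
  coordToSeq(k %/% 2^n, k %% 2^n, n, layout)
}

# dense occurrence-count vector (grid order) from the string-scan oracle
oracleCountsGridOrder <- function(motifs, n, layout = layoutATGC()) {
  bruteForceOccurrences(wordsInGridOrder(n, layout), motifs)
}
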