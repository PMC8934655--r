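test_that("buildCodebook matches the worked small cases", {
  expect_equal(length(buildCodebook(constraintSpec(2, maxHomopolymer = 1))),
               12L)                        # 4 * 3 non-repeating 2-mers
  expect_equal(length(buildCodebook(constraintSpec(3, motifs = "CC"))),
               57L)                        # 64 - 7 words containing CC
  b6 <- buildCodebook(constraintSpec(6, gcMin = 0.4, gcMax = 0.6))
  gc <- nchar(gsub("[AT]", "", codeWords(b6)))
  expect_true(all(gc == 3))                # only exactly 50% fits at n = 6
  expect_equal(length(b6), choose(6, 3) * 2^6)
})

test_that("homopolymer-free and single-letter-free counts are exact", {
  for (n in c(3, 5, 8))
    expect_equal(length(buildCodebook(constraintSpec(n, maxHomopolymer = 1))),
                 4 * 3^(n - 1))
  for (n in c(2, 4, 6))
    expect_equal(length(buildCodebook(constraintSpec(n, motifs = "A"))), 3^n)
})

test_that("codebooks are sorted, distinct, and constraint-clean", {
  spec <- constraintSpec(5, gcMin = 0.4, gcMax = 0.6, maxHomopolymer = 2,
                         motifs = "GAT")
  b <- buildCodebook(spec)
  w <- codeWords(b)
  expect_identical(w, sort(unique(w), method = "radix"))
  expect_false(any(grepl("GAT", w, fixed = TRUE)))
  expect_false(any(grepl("AAA|CCC|GGG|TTT", w)))
  gc <- nchar(gsub("[AT]", "", w)) / 5
  expect_true(all(gc >= 0.4 & gc <= 0.6))
})

test_that("enumeration equals the brute-force oracle on random specs", {
  specs <- randomConstraintSpecs(12, seed = 303, wordLengths = 4:7)
  for (spec in specs) {
    got <- codeWords(suppressWarnings(buildCodebook(spec)))
    want <- suppressWarnings(bruteForceCodebook(spec))
    expect_identical(got, want)
  }
})

test_that("constraints shrink monotonically", {
  base <- constraintSpec(5, maxHomopolymer = 2)
  b0 <- length(buildCodebook(base))
  b1 <- length(buildCodebook(constraintSpec(5, maxHomopolymer = 2,
                                            motifs = "CGA")))
  expect_lte(b1, b0)
  wide <- length(buildCodebook(constraintSpec(5, gcMin = 0.2, gcMax = 0.8)))
  narrow <- length(buildCodebook(constraintSpec(5, gcMin = 0.4, gcMax = 0.6)))
  expect_lte(narrow, wide)
  # contradictory spec: empty codebook with a warning, not an error
  expect_warning(b <- buildCodebook(constraintSpec(2, motifs = c("A", "C",
                                                                 "G", "T"))),
                 "empty")
  expect_equal(length(b), 0L)
  expect_error(buildCodebook(constraintSpec(13)), "cap")
})

test_that("concat-safe pruning removes exactly the junction-capable words", {
  # motif AAA: drop words ending with AA and words starting with AA
  b <- buildCodebook(constraintSpec(4))
  safe <- concatSafeFilter(b, motifs = "AAA")
  w <- codeWords(b)
  kept <- w[!(substr(w, 3, 4) == "AA" | substr(w, 1, 2) == "AA")]
  expect_identical(codeWords(safe), kept)
  expect_true("TAAT" %in% codeWords(safe))
  expect_true(safe@concatSafe)
})

test_that("surviving words concatenate without forbidden junctions", {
  motifs <- c("AAA", "CGCG")
  b <- concatSafeFilter(buildCodebook(constraintSpec(4, motifs = motifs)),
                        motifs = motifs)
  w <- codeWords(b)
  expect_gt(length(w), 0)
  expect_true(all(codeWords(b) %in% codeWords(buildCodebook(
    constraintSpec(4, motifs = motifs)))))
  # exhaustive ordered-pair junction scan
  pairs <- expand.grid(a = w, b = w, stringsAsFactors = FALSE)
  joined <- paste0(pairs$a, pairs$b)
  expect_false(any(grepl("AAA", joined, fixed = TRUE)))
  expect_false(any(grepl("CGCG", joined, fixed = TRUE)))
})

test_that("code rate follows log2(|C|)/n", {
  expect_equal(codeRate(codebook(wordsInGridOrder(2))), 2)
  expect_equal(codeRate(codebook("ACGT")), 0)
  expect_equal(codeRate(484263, n = 10), log2(484263) / 10)
  expect_equal(round(codeRate(484263, n = 10), 4), 1.8885)
  expect_error(codeRate(0, n = 4), "empty")
})

test_that("codebook FASTA round-trips through Biostrings", {
  b <- buildCodebook(constraintSpec(3, maxHomopolymer = 2))
  f <- tempfile(fileext = ".fasta")
  writeCodebook(b, f)
  r <- readCodebook(f)
  expect_identical(codeWords(r), codeWords(b))
  expect_equal(matrixOrder(r), 3L)

  # unsorted input is sorted with a message
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "TT", ">b", "AC"), f2)
  expect_message(r2 <- readCodebook(f2), "sort")
  expect_identical(codeWords(r2), c("AC", "TT"))

  # mixed lengths and bad alphabet are data errors
  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACG", ">b", "AC"), f3)
  expect_error(readCodebook(f3), "length")
  f4 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ANG"), f4)
  expect_error(readCodebook(f4), "outside")
})
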