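test_that("block size is the integer bit length minus one", {
  expect_equal(blockSize(484263), 18L)
  expect_equal(blockSize(2^12), 12L)
  expect_equal(blockSize(2), 1L)
  expect_equal(blockSize(3), 1L)
  expect_error(blockSize(1), "at least 2")
})

test_that("encoding indexes the sorted codebook lexicographically", {
  bb <- codebook(c("A", "C", "G", "T"))
  expect_identical(encodeBinary(as.raw(0x1b), bb, header = FALSE), "ACGT")
  expect_identical(decodeBinary("ACGT", bb, header = FALSE), as.raw(0x1b))
  # header-only encoding occupies ceil(64/b) words
  b5 <- codebook(wordsInGridOrder(3)[1:40])       # b = 5, n = 3
  dna <- encodeBinary(raw(0), b5)
  expect_equal(nchar(dna), ceiling(64 / 5) * 3)
  expect_identical(decodeBinary(dna, b5), raw(0))
  # output length formula for a payload
  payload <- as.raw(1:25)
  dna <- encodeBinary(payload, b5)
  expect_equal(nchar(dna), ceiling((64 + 8 * 25) / 5) * 3)
})

test_that("round trips are bit-exact across payloads and codebooks", {
  set.seed(99)
  books <- list(
    codebook(c("A", "C", "G", "T")),
    codebook(wordsInGridOrder(3)[1:40]),
    buildCodebook(constraintSpec(5, gcMin = 0.4, gcMax = 0.6,
                                 maxHomopolymer = 2)))
  for (book in books) {
    for (size in c(0, 1, 7, 128, 1000)) {
      payload <- as.raw(sample(0:255, size, replace = TRUE))
      dna <- encodeBinary(payload, book)
      expect_identical(decodeBinary(dna, book), payload)
      # every emitted word is addressable (index < 2^b)
      n <- matrixOrder(book)
      starts <- seq(1, nchar(dna), by = n)
      idx <- match(substring(dna, starts, starts + n - 1), codeWords(book))
      expect_true(all(idx - 1 < 2^blockSize(length(book))))
    }
  }
})

test_that("decoder rejects malformed input with located errors", {
  b5 <- codebook(wordsInGridOrder(3)[1:40])
  dna <- encodeBinary(as.raw(1:10), b5)
  expect_error(decodeBinary(substr(dna, 1, nchar(dna) - 1), b5), "framing")
  bad <- paste0("TTT", substr(dna, 4, nchar(dna)))   # TTT not in first 40
  expect_error(decodeBinary(bad, b5), "decode error|corruption")
  expect_error(decodeBinary(substr(dna, 1, 3), b5), "truncation")
  # a word beyond the addressable 2^b range is corruption
  book5 <- codebook(c("AA", "AC", "AG", "AT", "CA"))  # b = 2, index 4 illegal
  expect_error(decodeBinary("CACA", book5), "corruption")
})

test_that("realized rate approaches b/n from below", {
  b <- storageCodebook()
  expect_equal(blockSize(length(b)), 18L)
  payload <- as.raw(rep(165, 2250))
  dna <- encodeBinary(payload, b)
  # independent hand count: ceil((64 + 18000)/18) = 1004 blocks of 10 nt
  expect_equal(nchar(dna), 1004 * 10)
  expect_equal(realizedRate(payload, dna), 18000 / 10040)
  expect_lt(realizedRate(payload, dna), 18 / 10)
  expect_equal(realizedRate(raw(0), encodeBinary(raw(0), b)), 0)
  expect_error(realizedRate(as.raw(1), ""), "empty")
})
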