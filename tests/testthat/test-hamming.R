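# independent per-position string comparison
.stringHamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

test_that("single-nucleotide generators have one zero at the right corner", {
  expect_equal(b1Matrix("A"), rbind(c(0L, 1L), c(1L, 1L)))
  expect_equal(b1Matrix("T"), rbind(c(1L, 0L), c(1L, 1L)))
  expect_equal(b1Matrix("G"), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(b1Matrix("C"), rbind(c(1L, 1L), c(1L, 0L)))
  for (x in c("A", "C", "G", "T"))
    expect_equal(sum(b1Matrix(x) == 0L), 1L)
  expect_error(b1Matrix("N"))
})

test_that("hammingToWord equals brute-force distances", {
  expect_equal(as.matrix(hammingToWord("A")), b1Matrix("A"))
  H <- hammingToWord("AA")
  cc <- seqToCoord("CC")
  expect_equal(H@values[cc$row + 1, cc$col + 1], 2L)
  for (s in c("ACG", "TTTT", "GATC")) {
    n <- nchar(s)
    H <- as.matrix(hammingToWord(s))
    w <- wordsInGridOrder(n)
    want <- vapply(w, .stringHamming, numeric(1), a = s, USE.NAMES = FALSE)
    k <- 0:(4^n - 1)
    expect_equal(H[cbind(k %/% 2^n + 1, k %% 2^n + 1)], want)
    # own coordinate is at distance zero
    co <- seqToCoord(s)
    expect_equal(H[co$row + 1, co$col + 1], 0)
  }
})

test_that("distance histogram is choose(n,k) * 3^k", {
  s <- "ACGTAC"
  h <- table(factor(as.vector(as.matrix(hammingToWord(s))), levels = 0:6))
  expect_equal(as.numeric(h), choose(6, 0:6) * 3^(0:6))
})

test_that("pairwiseTable matches brute force, with metric invariants", {
  expect_equal(as.matrix(pairwiseTable(1)),
               matrix(1L, 4, 4) - diag(1L, 4))
  for (n in c(2, 3)) {
    Tn <- as.matrix(pairwiseTable(n))
    w <- wordsInGridOrder(n)
    want <- outer(seq_along(w), seq_along(w),
                  Vectorize(function(i, j) .stringHamming(w[i], w[j])))
    expect_equal(Tn, want, ignore_attr = TRUE)
    expect_true(all(diag(Tn) == 0))
    expect_identical(Tn, t(Tn))
  }
  # triangle inequality, exhaustive at n = 2
  T2 <- as.matrix(pairwiseTable(2))
  d <- dim(T2)[1]
  for (k in seq_len(d))
    expect_true(all(T2 <= outer(T2[, k], T2[k, ], `+`)))
})

test_that("a pairwise row equals the flattened single-word matrix", {
  for (s in c("AC", "GTA", "CCGG")) {
    n <- nchar(s)
    co <- seqToCoord(s)
    k <- co$row * 2^n + co$col
    Tn <- as.matrix(pairwiseTable(n))
    H <- as.matrix(hammingToWord(s))
    flat <- as.vector(t(H))   # grid order k = row * 2^n + col
    expect_equal(Tn[k + 1, ], flat, ignore_attr = TRUE)
  }
})
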