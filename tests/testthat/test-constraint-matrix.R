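test_that("motifMatrix starts from a single flagged cell", {
  M <- motifMatrix("CC", 2)
  expect_equal(matrixOrder(M), 2L)
  expect_equal(cbind(M@row, M@col, M@count), cbind(3, 3, 1))
  # only AAA contains AAA among 3-mers
  M3 <- motifMatrix("AAA", 3)
  expect_equal(cbind(M3@row, M3@col, M3@count), cbind(0, 0, 1))
})

test_that("motifMatrix counts overlapping occurrences exactly", {
  M <- motifMatrix("CC", 3)
  expect_equal(length(M@row), 7L)              # 7 of 64 words contain CC
  k <- M@row * 8 + M@col
  expect_equal(M@count[k == 63], 2)            # CCC at (7,7) twice
  expect_equal(M@count[k == 6 * 8 + 6], 1)     # ACC at (6,6) once
  # deeper orders stay exact: CCCC holds 3 overlapping CCs
  M4 <- motifMatrix("CC", 4)
  cccc <- seqToCoord("CCCC")
  expect_equal(M4@count[M4@row == cccc$row & M4@col == cccc$col], 3)
})

test_that("extendConstraint performs the literal tile+stretch step", {
  # empty matrices stay empty, order grows by one
  E <- new("ConstraintMatrix", order = 2L, row = numeric(0),
           col = numeric(0), count = numeric(0))
  expect_equal(matrixOrder(extendConstraint(E)), 3L)
  expect_length(extendConstraint(E)@row, 0L)

  # from the motif's own order the step is exact: all 2-mers containing A
  A2 <- extendConstraint(motifMatrix("A", 1))
  expect_equal(length(A2@row), 7L)
  w <- coordToSeq(A2@row, A2@col, 2)
  expect_setequal(w, grep("A", wordsInGridOrder(2), value = TRUE))
  expect_equal(A2@count[w == "AA"], 2)

  # dense cross-check of the sparse step against Matrix's Kronecker algebra
  skip_if_not_installed("Matrix")
  M <- motifMatrix("GT", 3)
  dense <- Matrix::Matrix(as.matrix(M), sparse = TRUE)
  ones <- Matrix::Matrix(1, 2, 2)
  want <- as.matrix(Matrix::kronecker(ones, dense) +
                    Matrix::kronecker(dense, ones))
  got <- as.matrix(extendConstraint(M))
  dimnames(want) <- NULL
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("matrix addition sums counts entrywise", {
  M <- motifMatrix("CC", 2)
  S <- addMatrices(M, M)
  expect_equal(S@count, 2)
  expect_equal(addMatrices(M, new("ConstraintMatrix", order = 2L,
                                  row = numeric(0), col = numeric(0),
                                  count = numeric(0)))@count, 1)
  expect_error(addMatrices(M, motifMatrix("CC", 3)), "order mismatch")
  # flagged set of a sum is the union of flagged sets
  A <- motifMatrix("AA", 3); B <- motifMatrix("CC", 3)
  AB <- A + B
  kA <- A@row * 8 + A@col; kB <- B@row * 8 + B@col
  expect_setequal(AB@row * 8 + AB@col, union(kA, kB))
})

test_that("occurrence counts agree with the string-scan oracle", {
  set.seed(42)
  motifs <- c("A", "CG", "TAT", "GGC", "ACCA")
  for (m in motifs) {
    n <- min(8L, nchar(m) + 4L)
    M <- motifMatrix(m, n)
    got <- numeric(4^n)
    got[M@row * 2^n + M@col + 1] <- M@count
    expect_equal(got, as.numeric(oracleCountsGridOrder(m, n)),
                 info = paste("motif", m))
  }
})

test_that("single-letter avoidance flags 4^n - 3^n cells", {
  for (n in 2:6)
    expect_equal(length(motifMatrix("A", n)@row), 4^n - 3^n)
})

test_that("extension raises order by one and never lowers a count", {
  M <- motifMatrix("CT", 2)
  for (i in 1:4) {
    M2 <- extendConstraint(M)
    expect_equal(matrixOrder(M2), matrixOrder(M) + 1L)
    # every old cell reappears in its four tiled images with >= its count
    off <- 2^matrixOrder(M)
    k2 <- M2@row * 2^matrixOrder(M2) + M2@col
    for (b in c(0, 1)) for (cc in c(0, 1)) {
      kt <- (M@row + b * off) * 2^matrixOrder(M2) + (M@col + cc * off)
      expect_true(all(M2@count[match(kt, k2)] >= M@count))
    }
    M <- M2
  }
})
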