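## collapse duplicate (row, col) cells by summing counts; returns canonical
## triplets sorted by linear index
.aggregateTriplets <- function(row, col, count, order) {
  k <- .coordIndex(row, col, order)
  agg <- rowsum(count, group = k, reorder = TRUE)
  kk <- as.numeric(rownames(agg))
  rc <- .indexCoord(kk, order)
  list(row = rc$row, col = rc$col, count = as.numeric(agg[, 1]))
}

.newConstraintMatrix <- function(order, row, col, count) {
  new("ConstraintMatrix", order = as.integer(order),
      row = as.numeric(row), col = as.numeric(col),
      count = as.numeric(count))
}

#' Sparse mCGR of a forbidden motif
#'
#' Builds the order-n constraint matrix of a motif by the fractal doubling
#' recursion: the motif's own mCGR (a single flagged cell at the motif's
#' coordinate) is grown one order at a time, at each step tiling the previous
#' matrix over the doubled grid (the appended letter takes the new coarsest
#' bits) and adding the end-anchored copy of the motif matrix (the stretched
#' initial matrix, flagging every word that ends with the motif). The count
#' stored at a cell therefore equals the number of possibly overlapping
#' occurrences of the motif in the word at that cell, and cells without an
#' entry are motif-free words.
#'
#' @param motif a DNA string over {A,C,G,T}.
#' @param n target order (word length), \code{n >= nchar(motif)}.
#' @param layout a [NucleotideLayout-class].
#' @param override set TRUE to lift the order cap.
#' @return a [ConstraintMatrix-class] of order n.
#' @examples
#' motifMatrix("CC", 2)   # single flagged cell (3, 3)
#' motifMatrix("CC", 3)   # 7 flagged cells; "CCC" carries count 2
#' @export
motifMatrix <- function(motif, n, layout = layoutATGC(), override = FALSE) {
  motif <- toupper(as.character(motif))
  if (length(motif) != 1L || !nzchar(motif)) stop("'motif' must be one DNA string")
  .checkAlphabet(motif, "motif")
  n <- as.integer(n)
  L <- nchar(motif)
  if (n < L) stop("'n' must be at least the motif length")
  .checkOrderCap(n, override = override)
  cm <- seqToCoord(motif, layout)
  r0 <- cm$row; c0 <- cm$col
  row <- r0; col <- c0; count <- 1
  ord <- L
  while (ord < n) {
    ## tile: append any letter at position ord + 1 (new coarsest bits)
    off <- 2^ord
    trow <- c(row, row + off, row, row + off)
    tcol <- c(col, col, col + off, col + off)
    tcnt <- rep(count, 4L)
    ## end-anchored motif: words of length ord + 1 whose last L letters are
    ## the motif; the leading ord + 1 - L letters are free (finest bits)
    free <- 2^(ord + 1L - L)
    f <- seq_len(free) - 1
    grid <- expand.grid(fr = f, fc = f)
    arow <- r0 * free + grid$fr
    acol <- c0 * free + grid$fc
    agg <- .aggregateTriplets(c(trow, arow), c(tcol, acol),
                              c(tcnt, rep(1, length(arow))), ord + 1L)
    row <- agg$row; col <- agg$col; count <- agg$count
    ord <- ord + 1L
  }
  .newConstraintMatrix(n, row, col, count)
}

#' One doubling step of the constraint recursion
#'
#' The literal tile-and-stretch step on a sparse constraint matrix M of order
#' n, returning the order n + 1 matrix 1 (x) M + M (x) 1: the tiling term
#' maps each flagged cell (r, q) to the four cells (r + b 2^n, q + c 2^n)
#' and the stretching term to the four cells (2r + b, 2q + c), b, c in
#' {0, 1}; coinciding images sum their counts. Applied to a matrix at the
#' flagged word's own order the resulting counts are exact occurrence counts;
#' under further iteration the flagged set (zero versus non-zero) remains
#' exact while interior occurrences are counted once per extension path, which
#' is why [motifMatrix()] anchors its appended term to the initial matrix
#' instead.
#'
#' @param M a [ConstraintMatrix-class] of order n.
#' @param override set TRUE to lift the order cap.
#' @return a [ConstraintMatrix-class] of order n + 1.
#' @examples
#' extendConstraint(motifMatrix("CC", 2))  # the 7 words containing CC
#' @export
extendConstraint <- function(M, override = FALSE) {
  stopifnot(is(M, "ConstraintMatrix"))
  n <- M@order
  .checkOrderCap(n + 1L, override = override)
  if (!length(M@row)) return(.newConstraintMatrix(n + 1L, numeric(0), numeric(0), numeric(0)))
  off <- 2^n
  b <- c(0, 1, 0, 1); cc <- c(0, 0, 1, 1)
  trow <- rep(M@row, times = 4L) + rep(b * off, each = length(M@row))
  tcol <- rep(M@col, times = 4L) + rep(cc * off, each = length(M@row))
  srow <- rep(2 * M@row, times = 4L) + rep(b, each = length(M@row))
  scol <- rep(2 * M@col, times = 4L) + rep(cc, each = length(M@row))
  cnt <- rep(M@count, times = 8L)
  agg <- .aggregateTriplets(c(trow, srow), c(tcol, scol), cnt, n + 1L)
  .newConstraintMatrix(n + 1L, agg$row, agg$col, agg$count)
}

#' Combine constraint matrices
#'
#' Entrywise sum of two sparse constraint matrices of equal order: the
#' combined matrix flags every word violating either constraint, with counts
#' accumulating. Also available as \code{A + B}.
#'
#' @param A,B [ConstraintMatrix-class] objects of equal order.
#' @param e1,e2 same, for the `+` operator.
#' @return a [ConstraintMatrix-class].
#' @examples
#' addMatrices(motifMatrix("AA", 3), motifMatrix("CC", 3))
#' @export
addMatrices <- function(A, B) {
  stopifnot(is(A, "ConstraintMatrix"), is(B, "ConstraintMatrix"))
  if (A@order != B@order)
    stop(sprintf("order mismatch: %d vs %d", A@order, B@order))
  agg <- .aggregateTriplets(c(A@row, B@row), c(A@col, B@col),
                            c(A@count, B@count), A@order)
  .newConstraintMatrix(A@order, agg$row, agg$col, agg$count)
}

#' @rdname addMatrices
#' @export
setMethod("+", signature("ConstraintMatrix", "ConstraintMatrix"),
          function(e1, e2) addMatrices(e1, e2))

## counts (0 = allowed) for every word index k = r * 2^n + q, as a vector of
## length 4^n; internal work-horse of codebook enumeration
.violationVector <- function(M) {
  v <- numeric(4^M@order)
  if (length(M@row))
    v[.coordIndex(M@row, M@col, M@order) + 1] <- M@count
  v
}
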