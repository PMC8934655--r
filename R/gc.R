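#' Homopolymer constraints as forbidden motifs
#'
#' A maximum homopolymer run of `maxRun` is equivalent to forbidding the four
#' motifs X^(maxRun + 1), X in {A,C,G,T}: the shortest forbidden runs, whose
#' exclusion also excludes every longer run. Reducing homopolymers to motifs
#' means one mechanism serves both constraints.
#'
#' @param maxRun maximum allowed run length (>= 1).
#' @return character vector of the 4 shortest forbidden runs.
#' @examples
#' homopolymerMotifs(2)  # AAA, CCC, GGG, TTT
#' @export
homopolymerMotifs <- function(maxRun) {
  maxRun <- as.integer(maxRun)
  if (length(maxRun) != 1L || is.na(maxRun) || maxRun < 1L)
    stop("'maxRun' must be a single integer >= 1")
  vapply(.DNA_LETTERS, function(x) strrep(x, maxRun + 1L), character(1),
         USE.NAMES = FALSE)
}

#' GC-count matrix by the doubling recursion
#'
#' Builds the dense 2^n x 2^n grid whose cell holds the GC count of the word
#' at that cell, via the generator recursion
#' \deqn{D^n = 1^{2^{n-1}} \otimes D^1 + D^{n-1} \otimes 1^2}
#' where the 2 x 2 generator D^1 marks the G/C corners of the layout:
#' \code{[[0,0],[1,1]]} for the default \code{[[A,T],[G,C]]} layout and
#' \code{[[0,1],[1,0]]} for \code{[[A,C],[G,T]]}. Dividing by n gives the GC
#' fraction of every word at once.
#'
#' @param n word length (dense construction, capped at 12 by default).
#' @param layout a [NucleotideLayout-class].
#' @param override set TRUE to lift the cap.
#' @return a [GcMatrix-class].
#' @examples
#' as.matrix(gcCountMatrix(1))  # the generator [[0,0],[1,1]]
#' @export
gcCountMatrix <- function(n, layout = layoutATGC(), override = FALSE) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  .checkOrderCap(n, cap = 12L, override = override)
  D1 <- .gcGenerator(layout)
  D <- D1
  if (n > 1L) {
    for (k in 2:n)
      D <- kronecker(matrix(1L, 2^(k - 1), 2^(k - 1)), D1) +
           kronecker(D, matrix(1L, 2, 2))
  }
  storage.mode(D) <- "integer"
  new("GcMatrix", order = n, values = D, layout = layout)
}

.gcGenerator <- function(layout) {
  g <- matrix(0L, 2, 2)
  g[layout@letters %in% c("G", "C")] <- 1L
  g
}

## continued-fraction rationalisation of a user-supplied bound, so that GC
## interval tests run in exact integer arithmetic (0.4 -> 2/5, not the
## nearest binary double)
.asRational <- function(x, maxDen = 1000000L) {
  if (is.na(x)) return(c(NA_real_, NA_real_))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > maxDen) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps * max(1, x)) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(sign * p1, q1)
}

#' Inclusive GC-interval test on integer GC counts
#'
#' Decides whether a word with `gcCount` G/C characters out of `n` satisfies
#' the inclusive bounds gcMin <= gcCount/n <= gcMax. Bounds are rationalized
#' and compared in exact integer arithmetic, so e.g. gcCount 4 of n = 10
#' passes a 0.4 lower bound exactly. An NA bound is unconstrained.
#'
#' @param gcCount integer vector of GC counts in [0, n].
#' @param n word length.
#' @param gcMin,gcMax inclusive fraction bounds, or NA.
#' @return logical vector.
#' @examples
#' gcAllowed(4, 10, 0.4, 0.6)  # TRUE: the 4-6 option at n = 10
#' gcAllowed(3, 10, 0.4, 0.6)  # FALSE
#' @export
gcAllowed <- function(gcCount, n, gcMin = NA, gcMax = NA) {
  if (any(gcCount < 0 | gcCount > n)) stop("'gcCount' must lie in [0, n]")
  ok <- rep(TRUE, length(gcCount))
  if (!is.na(gcMin)) {
    r <- .asRational(gcMin)
    ok <- ok & (gcCount * r[2] >= r[1] * n)
  }
  if (!is.na(gcMax)) {
    r <- .asRational(gcMax)
    ok <- ok & (gcCount * r[2] <= r[1] * n)
  }
  ok
}
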