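#' Corner layouts for the chaos-game square
#'
#' `nucleotideLayout()` builds a [NucleotideLayout-class] from a 2 x 2
#' character matrix giving the nucleotide at each (row bit, column bit)
#' corner. `layoutATGC()` is the default layout \code{[[A,T],[G,C]]} (A top
#' left, T top right, G bottom left, C bottom right); `layoutACGT()` is the
#' alternate \code{[[A,C],[G,T]]} ordering, under which the 50% GC cells form
#' flower-like rather than striped patterns.
#'
#' @param letters 2 x 2 character matrix over {A,C,G,T}.
#' @return a [NucleotideLayout-class].
#' @examples
#' layoutATGC()
#' nucleotideLayout(rbind(c("A", "C"), c("G", "T")))
#' @export
nucleotideLayout <- function(letters) {
  new("NucleotideLayout", letters = letters)
}

#' @rdname nucleotideLayout
#' @export
layoutATGC <- function() {
  nucleotideLayout(rbind(c("A", "T"), c("G", "C")))
}

#' @rdname nucleotideLayout
#' @export
layoutACGT <- function() {
  nucleotideLayout(rbind(c("A", "C"), c("G", "T")))
}

## (row bit, col bit) of each nucleotide, as a named list of c(row, col)
.layoutBits <- function(layout) {
  l <- layout@letters
  bits <- list()
  for (r in 0:1) for (c in 0:1) bits[[l[r + 1, c + 1]]] <- c(r, c)
  bits
}

## letter at quadrant index 2*rowbit + colbit (0..3)
.layoutQuadrantLetters <- function(layout) {
  l <- layout@letters
  c(l[1, 1], l[1, 2], l[2, 1], l[2, 2])
}

.checkAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("invalid character in %s '%s': alphabet is {A,C,G,T}",
                 what, x[which(bad)[1]]), call. = FALSE)
  invisible(x)
}

## Default hard cap on the mCGR order; dense 4^n enumeration beyond ~12-14 is
## impractical, mirroring the observed practical limit of the method.
.DEFAULT_ORDER_CAP <- 14L

.checkOrderCap <- function(n, cap = .DEFAULT_ORDER_CAP, override = FALSE) {
  if (!override && n > cap)
    stop(sprintf(
      "word length %d exceeds the cap of %d; pass override = TRUE if you really want this",
      n, cap), call. = FALSE)
  invisible(n)
}
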