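#' Classic chaos game representation with exact dyadic coordinates
#'
#' Runs the iterative midpoint rule on the unit square [-1, 1]^2: starting
#' from the origin, each nucleotide moves the current point halfway towards
#' its corner, producing one point per character. Corners follow the layout,
#' with the column bit on the x axis (0 -> -1, 1 -> +1) and the row bit on
#' the y axis (0 -> +1, 1 -> -1); the default layout therefore puts
#' A = (-1, +1), T = (+1, +1), G = (-1, -1), C = (+1, -1).
#'
#' After k steps the coordinates are dyadic rationals num / 2^k with
#' |num| < 2^k; they are kept exactly as (numerator, power-of-two
#' denominator) pairs, which doubles also represent without rounding up to
#' k = 52. Longer sequences are refused rather than silently rounded.
#'
#' @param seq one DNA string (possibly empty), alphabet {A,C,G,T}, at most 52
#'   characters.
#' @param layout a [NucleotideLayout-class].
#' @return a data.frame with one row per character: exact numerators
#'   `numX`, `numY`, the common denominator `den` = 2^step, and the (exact)
#'   numeric coordinates `x`, `y`.
#' @examples
#' cgrPoints("C")    # (1/2, -1/2)
#' cgrPoints("CA")   # then (-1/4, 1/4)
#' @export
cgrPoints <- function(seq, layout = layoutATGC()) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("'seq' must be a single string")
  k <- nchar(seq)
  empty <- data.frame(numX = numeric(0), numY = numeric(0), den = numeric(0),
                      x = numeric(0), y = numeric(0))
  if (k == 0L) return(empty)
  if (k > 52L)
    stop("sequences longer than 52 nt exceed the exact dyadic range")
  .checkAlphabet(seq)
  bits <- .layoutBits(layout)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nx <- ny <- numeric(k)
  px <- py <- 0
  for (i in seq_len(k)) {
    b <- bits[[chars[i]]]
    cx <- if (b[2] == 0) -1 else 1
    cy <- if (b[1] == 0) 1 else -1
    ## p_i = (p_{i-1} + corner) / 2 over the common denominator 2^i
    px <- px + cx * 2^(i - 1)
    py <- py + cy * 2^(i - 1)
    nx[i] <- px
    ny[i] <- py
  }
  den <- 2^seq_len(k)
  data.frame(numX = nx, numY = ny, den = den, x = nx / den, y = ny / den)
}
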