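#' Export mCGR-derived matrices as CSV or PGM
#'
#' Writes a dense matrix view of a [ConstraintMatrix-class] (violation
#' counts, 0 = allowed word), [GcMatrix-class], [HammingMatrix-class] or
#' [PairwiseTable-class] either as a headerless CSV of integers or as an
#' ASCII PGM grayscale raster (P2), in which the fractal patterns - the
#' Sierpinski triangle of a single forbidden letter, the T-square of other
#' motifs, GC stripes - are directly visible. Output is deterministic and
#' byte-identical across runs.
#'
#' @param x the matrix object to export.
#' @param path output file path.
#' @param format "csv" or "pgm".
#' @param maxOrder refuse dense export above this order (default 8).
#' @return the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' exportMatrix(gcCountMatrix(1), f)  # writes "0,0" and "1,1"
#' readLines(f)
#' @export
exportMatrix <- function(x, path, format = c("csv", "pgm"), maxOrder = 8L) {
  format <- match.arg(format)
  if (matrixOrder(x) > maxOrder)
    stop(sprintf("dense export is limited to order <= %d", maxOrder))
  m <- as.matrix(x)
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE, eol = "\n")
  } else {
    mx <- max(m, 1L)
    con <- file(path, open = "wb")  # binary mode: fixed \n on every platform
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(mx),
                 apply(m, 1L, paste, collapse = " ")),
               con, sep = "\n")
  }
  invisible(path)
}
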