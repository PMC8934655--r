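#' @rdname matrixOrder
#' @export
setGeneric("matrixOrder", function(x) standardGeneric("matrixOrder"))

#' @rdname codeWords
#' @export
setGeneric("codeWords", function(x) standardGeneric("codeWords"))

#' @rdname codeRate
#' @export
setGeneric("codeRate", function(x, ...) standardGeneric("codeRate"))

#' Order (word length) of an mCGR-derived object
#'
#' @param x a [ConstraintMatrix-class], [GcMatrix-class],
#'   [HammingMatrix-class], [PairwiseTable-class], [ConstraintSpec-class] or
#'   [Codebook-class].
#' @return the word length n the object describes.
#' @examples
#' matrixOrder(motifMatrix("CC", 3))
#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "ConstraintMatrix", function(x) x@order)

#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "GcMatrix", function(x) x@order)

#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "HammingMatrix", function(x) x@order)

#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "PairwiseTable", function(x) x@wordLength)

#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "ConstraintSpec", function(x) x@wordLength)

#' @rdname matrixOrder
#' @export
setMethod("matrixOrder", "Codebook", function(x) x@wordLength)

#' Code words of a codebook
#'
#' @param x a [Codebook-class].
#' @return character vector of sorted code words.
#' @rdname codeWords
#' @export
setMethod("codeWords", "Codebook", function(x) x@words)

#' @describeIn codeWords number of code words.
#' @export
setMethod("length", "Codebook", function(x) length(x@words))

#' Dense matrix views
#'
#' `as.matrix` densifies the sparse [ConstraintMatrix-class] (zeros are
#' allowed words) and unwraps the value grids of the dense classes.
#'
#' @param x the object to densify.
#' @param ... ignored.
#' @return a base integer matrix.
#' @export
setMethod("as.matrix", "ConstraintMatrix", function(x, ...) {
  d <- as.integer(2^x@order)
  if (d > 4096L)
    stop("refusing to densify a ConstraintMatrix of order > 12")
  m <- matrix(0L, d, d)
  m[cbind(x@row + 1, x@col + 1)] <- as.integer(x@count)
  m
})

#' @rdname as.matrix-ConstraintMatrix-method
#' @export
setMethod("as.matrix", "GcMatrix", function(x, ...) x@values)

#' @rdname as.matrix-ConstraintMatrix-method
#' @export
setMethod("as.matrix", "HammingMatrix", function(x, ...) x@values)

#' @rdname as.matrix-ConstraintMatrix-method
#' @export
setMethod("as.matrix", "PairwiseTable", function(x, ...) x@values)

setMethod("show", "NucleotideLayout", function(object) {
  l <- object@letters
  cat("NucleotideLayout  [[", l[1, 1], ",", l[1, 2], "], [",
      l[2, 1], ",", l[2, 2], "]]\n", sep = "")
})

setMethod("show", "ConstraintMatrix", function(object) {
  cat(sprintf("ConstraintMatrix of order %d (%d x %d): %d flagged cell(s)\n",
              object@order, 2^object@order, 2^object@order,
              length(object@row)))
})

setMethod("show", "GcMatrix", function(object) {
  cat(sprintf("GcMatrix of order %d (%d x %d)\n",
              object@order, 2^object@order, 2^object@order))
})

setMethod("show", "HammingMatrix", function(object) {
  cat(sprintf("HammingMatrix: distances to '%s' (order %d)\n",
              object@reference, object@order))
})

setMethod("show", "PairwiseTable", function(object) {
  cat(sprintf("PairwiseTable: %d x %d Hamming distances, word length %d\n",
              4^object@wordLength, 4^object@wordLength, object@wordLength))
})

setMethod("show", "ConstraintSpec", function(object) {
  gc <- if (is.na(object@gcMin) && is.na(object@gcMax)) "unconstrained"
        else sprintf("[%s, %s]",
                     ifelse(is.na(object@gcMin), "0", format(object@gcMin)),
                     ifelse(is.na(object@gcMax), "1", format(object@gcMax)))
  hp <- if (is.na(object@maxHomopolymer)) "unconstrained"
        else sprintf("<= %d", object@maxHomopolymer)
  cat(sprintf("ConstraintSpec: word length %d, GC %s, homopolymer runs %s, %d motif(s)\n",
              object@wordLength, gc, hp, length(object@motifs)))
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d word(s) of length %d%s\n",
              length(object@words), object@wordLength,
              if (isTRUE(object@concatSafe)) ", concatenation-safe" else ""))
  if (length(object@words)) {
    head <- utils::head(object@words, 4L)
    cat("  ", paste(head, collapse = " "),
        if (length(object@words) > 4L) " ..." else "", "\n", sep = "")
    cat(sprintf("  code rate: %.4f bits/nt\n", codeRate(object)))
  }
})
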