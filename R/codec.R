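#' Block size of a lexicographic codebook
#'
#' Number of payload bits carried per code word: b = floor(log2(|C|)),
#' computed by integer bit length (never floating-point logarithms), so only
#' the first 2^b words of the sorted codebook are ever addressed.
#'
#' @param codebookSize number of code words, >= 2.
#' @return integer block size b.
#' @examples
#' blockSize(484263)  # 18
#' blockSize(2^12)    # 12
#' @export
blockSize <- function(codebookSize) {
  codebookSize <- as.numeric(codebookSize)
  if (length(codebookSize) != 1L || is.na(codebookSize) || codebookSize < 2)
    stop("a codebook must have at least 2 words to carry information")
  b <- 0L
  while (2^(b + 1L) <= codebookSize) b <- b + 1L
  b
}

## bits of a raw vector, MSB-first within each byte, as an integer vector
.rawToBitsMsb <- function(payload) {
  if (!length(payload)) return(integer(0))
  m <- matrix(as.integer(rawToBits(payload)), nrow = 8L)  # LSB-first rows
  as.integer(m[8:1, ])
}

.bitsMsbToRaw <- function(bits) {
  if (length(bits) %% 8L != 0L) stop("bit count must be a multiple of 8")
  if (!length(bits)) return(raw(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  packBits(as.integer(m[8:1, ]), type = "raw")
}

## 64-bit big-endian bits of a non-negative integer value (< 2^53)
.lengthHeaderBits <- function(value) {
  as.integer(value %/% 2^(63:0) %% 2)
}

#' Lexicographic binary-to-DNA encoding
#'
#' Encodes an arbitrary byte payload as a concatenation of code words: the
#' bit stream (an optional 64-bit big-endian payload-bit-length header,
#' followed by the payload bytes MSB-first) is partitioned into b-bit blocks
#' (b from [blockSize()]), the final partial block is zero-padded on the
#' right, and each block value v indexes word v of the lexicographically
#' sorted codebook. The output length is ceil((64 + 8 |payload|) / b) * n
#' nucleotides with the header, ceil(8 |payload| / b) * n without.
#'
#' The header travels through the same block mechanism as the payload and
#' lets [decodeBinary()] discard pad bits exactly; disable it only for
#' worked examples and rate experiments where the payload length is known
#' out of band.
#'
#' @param payload a raw vector (use [readBin()] for files).
#' @param book a [Codebook-class] with at least 2 words.
#' @param header include the 64-bit length header (default TRUE).
#' @return a single DNA string.
#' @examples
#' encodeBinary(as.raw(0x1b), codebook(c("A", "C", "G", "T")),
#'              header = FALSE)  # "ACGT"
#' @export
encodeBinary <- function(payload, book, header = TRUE) {
  stopifnot(is.raw(payload), is(book, "Codebook"))
  if (length(book) < 2L) stop("codebook must contain at least 2 words")
  b <- blockSize(length(book))
  bits <- .rawToBitsMsb(payload)
  if (header)
    bits <- c(.lengthHeaderBits(8 * length(payload)), bits)
  pad <- (-length(bits)) %% b
  if (pad) bits <- c(bits, integer(pad))
  if (!length(bits)) return("")
  blocks <- matrix(bits, nrow = b)
  v <- as.numeric(2^((b - 1):0) %*% blocks)
  paste(book@words[v + 1], collapse = "")
}

#' Lexicographic DNA-to-binary decoding
#'
#' Inverse of [encodeBinary()]: the DNA string is split into words of the
#' codebook's length, each word is mapped to its index in the sorted
#' codebook (a word absent from the codebook is a decode error naming its
#' nucleotide offset; an index >= 2^b, which the encoder never emits, is a
#' corruption error), the b-bit blocks are reassembled into the bit stream,
#' and the header (when present) determines exactly how many payload bits to
#' return, discarding the right pad. Without a header, all complete bytes
#' are returned.
#'
#' @param dna a single DNA string, length divisible by the word length.
#' @param book the [Codebook-class] used for encoding.
#' @param header expect the 64-bit length header (default TRUE).
#' @return the payload as a raw vector.
#' @export
decodeBinary <- function(dna, book, header = TRUE) {
  stopifnot(is.character(dna), length(dna) == 1L, is(book, "Codebook"))
  if (length(book) < 2L) stop("codebook must contain at least 2 words")
  n <- book@wordLength
  b <- blockSize(length(book))
  len <- nchar(dna)
  if (len %% n != 0L)
    stop(sprintf("framing error: %d nt is not a multiple of the word length %d",
                 len, n))
  if (len == 0L) {
    if (header) stop("truncation error: no room for the length header")
    return(raw(0))
  }
  starts <- seq.int(1L, len, by = n)
  wordvec <- substring(dna, starts, starts + n - 1L)
  idx <- match(wordvec, book@words)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("decode error: word '%s' at nucleotide offset %d is not in the codebook",
                 wordvec[i], starts[i] - 1L))
  }
  v <- idx - 1
  if (any(v >= 2^b)) {
    i <- which(v >= 2^b)[1]
    stop(sprintf("corruption error: word '%s' at nucleotide offset %d has index %.0f >= 2^%d",
                 wordvec[i], starts[i] - 1L, v[i], b))
  }
  bits <- integer(b * length(v))
  for (i in seq_len(b))
    bits[seq.int(i, by = b, length.out = length(v))] <- v %/% 2^(b - i) %% 2
  if (header) {
    if (length(bits) < 64L)
      stop("truncation error: fewer than 64 bits, no length header")
    payloadBits <- sum(bits[1:64] * 2^(63:0))
    if (payloadBits %% 8 != 0)
      stop("corruption error: declared payload length is not a whole number of bytes")
    if (64 + payloadBits > length(bits))
      stop(sprintf("truncation error: header declares %.0f payload bits but only %d are present",
                   payloadBits, length(bits) - 64L))
    bits <- bits[seq_len(payloadBits) + 64L]
  } else {
    bits <- bits[seq_len(8L * (length(bits) %/% 8L))]
  }
  .bitsMsbToRaw(bits)
}

#' Realized encoding rate
#'
#' Payload bits per output nucleotide, 8 |payload| / nchar(dna). The 64-bit
#' length header is excluded from the numerator (it is framing, not
#' payload), so the realized rate is bounded by b/n and approaches it as the
#' payload grows.
#'
#' @param payload the raw payload that was encoded.
#' @param dna the DNA string produced by [encodeBinary()].
#' @return rate in bits per nucleotide.
#' @export
realizedRate <- function(payload, dna) {
  stopifnot(is.raw(payload), is.character(dna), length(dna) == 1L)
  if (!nchar(dna)) stop("empty encoding")
  8 * length(payload) / nchar(dna)
}
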