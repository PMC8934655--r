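#' Build a constraint specification
#'
#' Collects the constraints a codebook must satisfy. GC bounds are inclusive
#' fractions in [0, 1] (use `gcMin == gcMax` for a fixed GC content);
#' `maxHomopolymer` is the longest allowed run of identical nucleotides;
#' `motifs` are forbidden anywhere within a word.
#'
#' @param wordLength code word length n.
#' @param gcMin,gcMax inclusive GC fraction bounds, or NA for unconstrained.
#' @param maxHomopolymer longest allowed run, or NA for unconstrained.
#' @param motifs character vector of forbidden motifs (case-folded,
#'   duplicates dropped).
#' @param layout a [NucleotideLayout-class].
#' @return a [ConstraintSpec-class].
#' @examples
#' constraintSpec(10, gcMin = 0.4, gcMax = 0.6, maxHomopolymer = 3)
#' @export
constraintSpec <- function(wordLength, gcMin = NA, gcMax = NA,
                           maxHomopolymer = NA, motifs = character(0),
                           layout = layoutATGC()) {
  motifs <- unique(toupper(as.character(motifs)))
  new("ConstraintSpec",
      wordLength = as.integer(wordLength),
      gcMin = as.numeric(gcMin), gcMax = as.numeric(gcMax),
      maxHomopolymer = as.integer(maxHomopolymer),
      motifs = motifs, layout = layout)
}

## spec motifs plus the homopolymer-derived motifs, deduplicated
.effectiveMotifs <- function(spec) {
  m <- spec@motifs
  if (!is.na(spec@maxHomopolymer))
    m <- c(m, homopolymerMotifs(spec@maxHomopolymer))
  unique(m)
}

#' Read forbidden motifs from a FASTA file
#'
#' Reads a plain multi-record FASTA of motifs, upper-cases the sequences,
#' enforces the strict {A,C,G,T} alphabet (ambiguity codes are rejected,
#' naming the offending record), drops duplicates and preserves the original
#' record order. An empty file yields an empty motif list with a warning.
#'
#' @param path path to a FASTA file.
#' @return character vector of motifs.
#' @export
loadMotifs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (!length(set)) {
    warning(sprintf("no motifs found in '%s'", path))
    return(character(0))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "motif record '%s' contains characters outside {A,C,G,T}",
      if (nzchar(names(set)[i])) names(set)[i] else as.character(i)),
      call. = FALSE)
  }
  unique(unname(seqs))
}
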