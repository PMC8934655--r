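Package: ConstrainedCGR
Title: Fractal Construction of Constrained DNA Code Words
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs DNA codebooks that satisfy synthesis and sequencing
    constraints (GC content, maximum homopolymer run length, arbitrary
    forbidden motifs) by a Kronecker-style fractal recursion on the matrix
    chaos game representation (mCGR) of all DNA words of a fixed length.
    Also provides Hamming-distance matrices built by the same recursion,
    exact-rational classic chaos game representation coordinates,
    concatenation-safe codebook pruning, and a lexicographic codec that maps
    arbitrary binary payloads onto concatenated code words. Codebooks and
    motif sets are exchanged as plain FASTA via Biostrings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Biostrings
Suggests: testthat (>= 3.0.0), Matrix, jsonlite, optparse
biocViews: DataRepresentation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
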