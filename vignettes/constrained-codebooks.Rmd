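---
title: "Constrained DNA codebooks from fractal matrix recursions"
author: "ConstrainedCGR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained DNA codebooks from fractal matrix recursions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConstrainedCGR)
```

## The model

A DNA word of length $n$ over $\{A,C,G,T\}$ is identified with one cell of
the $2^n \times 2^n$ matrix chaos game representation (mCGR) grid. The
package fixes the bit convention as: character $i$ of the word (counted from
the start) supplies bit $i-1$ of both the row and the column index, with the
(row bit, column bit) of each letter given by a corner layout, by default
$[[A,T],[G,C]]$. The first character therefore sets the finest bits and the
last character the coarsest, which makes the grid self-similar — all words
in one quadrant share their final letter — and is the property every
recursion below relies on. The convention is a genuine choice (the
quadrant-sharing property alone does not fix it); this one reproduces the
standard worked grid in which the order-2 top row reads AA, TA, AT, TT.

### Constraint propagation

A forbidden motif $m$ of length $L$ starts as a single flagged cell in the
order-$L$ grid. One doubling step consists of *tiling* (the four copies of
the matrix under appending any letter at the new, coarsest position) and the
*end-anchored* term that flags every word of the new order ending with $m$,
i.e. the $(ord+1-L)$-fold stretch of the initial motif matrix. Iterating to
order $n$ yields, at every cell, exactly the number of possibly overlapping
occurrences of $m$ in that cell's word; cells with no entry are motif-free.
Only flagged positions are stored (triplet sparse form): the allowed set is
the complement and is never sparse, so it is materialized only at
enumeration time.

A subtlety worth recording: the textbook one-step form of this recursion —
tile *and* stretch the same matrix, available as `extendConstraint()` — is
exact when applied at the motif's own order, and its flagged *set* (zero
versus non-zero) stays exact forever, but from order $L+2$ onwards it counts
interior occurrences once per extension path (CCCC would get 4, not 3, for
motif CC). Since the package promises occurrence counts, `motifMatrix()`
anchors the appended term to the initial matrix instead, which is exact at
every order. Both routes are tested; the exhaustive string-scan oracle pins
the counts for every motif of length ≤ 4 at order 8.

Homopolymer limits are not a separate mechanism: a maximum run of $r$
identical letters is the four forbidden motifs $X^{r+1}$
(`homopolymerMotifs()`), because excluding the shortest forbidden run
excludes all longer ones. Multiple constraints add entrywise.

### GC content and Hamming distance

With the 2 × 2 generator $D^1$ marking the layout's G/C corners
($[[0,0],[1,1]]$ for the default layout), the recursion
$D^n = \mathbb{1}^{2^{n-1}} \otimes D^1 + D^{n-1} \otimes \mathbb{1}^2$
produces the dense grid of per-word GC counts; dividing by $n$ gives the GC
fraction of all $4^n$ words at once. The same recursion with the
per-nucleotide generator $B^1$ (0 at the nucleotide's corner, 1 elsewhere)
gives Hamming distances from a reference word to all words, and with the
4 × 4 ones-minus-identity generator the full $4^n \times 4^n$ pairwise
table. The pairwise recursion naturally indexes words by per-character
base-4 digits; the package permutes the result to the grid-linear index
$k = \mathrm{row}\cdot 2^n + \mathrm{col}$ so that rows of the table align
with flattened single-word matrices — the word ordering is otherwise
arbitrary, and this choice keeps every module consistent.

### Codebooks, junction safety, and the codec

`buildCodebook()` enumerates all $4^n$ cells, keeps those with zero
violation count and an admissible GC count, back-calculates cell positions
to sequences, and sorts them with A < C < G < T. The alphabet order is a
free choice (any fixed order yields the same code rate and a self-consistent
codec); ASCII order is used because it matches `sort()` in the C locale.

`concatSafeFilter()` makes a codebook safe for free concatenation. A
junction occurrence of a motif of length $L$ splits into $k_1$ leading motif
letters ending the first word and $k_2 = L - k_1$ trailing motif letters
starting the second. The filter drops words whose suffix matches the motif
start at length $\ge \lceil L/2\rceil$ and words whose prefix matches the
motif end at length $\ge L+1-\lceil L/2\rceil$. Every split then triggers at
least one rule, so the property holds for all ordered pairs (tested
exhaustively at small $n$) — and because the two thresholds are
complementary ($a + b = L + 1$), no word is removed that a junction could
never implicate. For odd $L$ both thresholds coincide at $(L+1)/2$: for the
run AAA exactly the words ending with AA and those starting with AA are
dropped. For even $L$ a symmetric $\lceil L/2\rceil$-on-both-sides rule
would also be safe but strictly smaller; the minimal rule is preferred, and
it is what reproduces the reference code rate below.

The codec maps $b = \lfloor \log_2 |C| \rfloor$ bit blocks (computed by
integer bit length, never floating point) to codebook indices. Termination
is the package's own design: a 64-bit big-endian payload-bit-length header
travels through the same block mechanism, so the decoder can discard right
pad bits exactly; `header = FALSE` exists for worked examples where the
length is known out of band. Bit order is MSB-first at both byte and block
level. Indices $\ge 2^b$ are never emitted and are treated as corruption on
decode.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| corner layout | $[[A,T],[G,C]]$ | the standard worked grid; $[[A,C],[G,T]]$ preset included since the two produce different GC patterns |
| GC bounds | unset (unconstrained) | inclusive; `gcMin == gcMax` expresses fixed GC; bounds are rationalized (continued fractions, denominator ≤ 10⁶) so 0.4 means 2/5 exactly and count-versus-bound tests run in integer arithmetic |
| `maxHomopolymer` | unset | a run limit of $r$ forbids the four motifs of length $r+1$ |
| enumeration cap | $n \le 12$ | the $4^n$ enumeration and dense GC grid grow fourfold per step; ~12 nt is where whole-codebook enumeration stops being practical on ordinary hardware, and the code rate gained beyond 10 nt is marginal. `override = TRUE` lifts it |
| single-word Hamming cap | $n \le 10$; pairwise $n \le 6$ | dense $2^n\times 2^n$ / $4^n \times 4^n$ storage |
| CGR points | ≤ 52 nt | coordinates after $k$ steps are dyadic rationals $num/2^k$, $|num| < 2^k$, held exactly in (numerator, denominator) pairs; 52 is where doubles stop being exact, and the package refuses longer input rather than silently rounding |

## What the generators and tests do (and do not) show

`randomConstraintSpecs()` draws the constraint space the tests sweep: GC
from {unconstrained, [0.4, 0.6], exactly 0.5}, run limits {1, 2, 3,
unconstrained}, 0–3 random motifs of length 2–4 — the regimes practically
relevant for synthesis (40–60% GC and short run limits are the standard
envelope). `makeFixtures()` emulates a benchmark corpus with seeded random
byte blobs; content is irrelevant to a lossless codec, so randomness loses
nothing, but timing figures on such blobs say nothing about compressibility
of real files (the codec does not compress).

Every recursion is verified against an independent route that shares no
code with it: string scans for occurrence counts and codebook membership,
per-position character comparison for distances, popcount closed forms for
GC, and `Matrix::kronecker` for the literal tile+stretch step. Problem sizes
used by the test suite: exhaustive grids to order 8 (65,536 words), all 340
motifs of length ≤ 4 at order 8, 50 random specs against the brute-force
enumerator, the full length-10 storage codebook (1,048,576 cells
enumerated), and 100 random payloads of 1–10 kB through the codec. These
sizes exercise every code path at the scale the method is designed for;
they do not probe the memory ceiling of the $n = 12$ cap.

## Reference figures the package reproduces

The reference storage codebook (length 10, GC 40–60%, runs ≤ 3,
concatenation-safe) enumerates to 488,584 words, code rate
$\log_2(488584)/10 = 1.8898$ bits/nt, block size 18, and a realized
payload rate of 1.80 bits/nt on a 1 MiB payload — recomputed end-to-end by
`scripts/acceptance.R`. A symmetric junction rule would prune the same
constraints more aggressively and lose measurable rate; the minimal rule
keeps every word a junction can never implicate, which is why it is the
default and only behaviour.

## Known limitations

- Whole-codebook enumeration is exponential in $n$; the method is for short
  code words (≤ ~12 nt), not for constraint-checking long sequences.
- Only substring constraints, run limits and GC windows are expressible:
  no melting temperature, secondary structure, $k$-mer uniqueness or
  minimum pairwise distance selection (the Hamming tables describe
  distances; they do not construct distance-$d$ codes).
- Reverse-complement occurrences of a motif are not excluded unless the
  reverse complement is itself listed as a motif.
- The codec is a plain fixed-rate map with no error correction; it is meant
  to compose with an outer code, not to replace one.
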