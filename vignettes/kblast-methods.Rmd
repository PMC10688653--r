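---
title: "kblast: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kblast: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kblast)
```

This vignette is the package's own account of what it computes and why
the open design choices were made the way they were. The search is the
classic BLAST-like heuristic chain — k-mer candidate filtering followed
by seed-and-extend local alignment — implemented so that every stage is
individually callable and testable.

## The model

A search compares a query q against database sequences t over a shared
alphabet. The pipeline makes two approximations relative to exhaustive
optimal local alignment, and everything else is exact given them:

1. **Candidate filtering.** Only database sequences sharing at least
   one k-mer with the query are considered, in decreasing order of
   U(q, t) = |K(q) ∩ K(t)|, where K(·) is the set of *distinct*,
   ambiguity-free k-mers of a sequence. The assumption is the standard
   word-count heuristic: homologous sequences share many exact words.
   At the default k = 8 (DNA), a pair must conserve at least one exact
   8-mer to be found at all; at very high divergence (beyond roughly
   35–40%) that assumption fails and the pair is invisible to the
   search. This is inherent to the method, not a defect of the
   implementation.
2. **Seed-and-extend with greedy chaining.** Within a candidate pair,
   alignment is reconstructed from exact k-mer seeds: ungapped X-drop
   extension produces high-scoring segment pairs (HSPs), the HSPs are
   chained greedily (highest-scoring first, then the best remaining
   HSP collinear and non-overlapping with everything already
   selected), and the inter-HSP gaps are closed by banded affine-gap
   global dynamic programming. The result approximates — and on
   well-behaved inputs matches — a full local alignment, at a fraction
   of the cost.

Identity, the accept/reject statistic, is defined as matching columns
divided by *all* alignment columns including gap columns, computed over
the span from the first chained HSP's start to the last one's end.
Terminal unaligned overhangs are excluded. The definition is a
deliberate choice (the quantity has no universal definition); it
matches what users of tabular BLAST output expect. One consequence
worth knowing: because X-drop extension trims alignments back to their
best-scoring endpoints, a moderately diverged pair can yield a shorter,
higher-identity alignment rather than a full-length, lower-identity
one. Identity thresholds therefore act on the *reported local
alignment*, not on whole-sequence identity.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `k` | 8 (DNA), 5 (protein) | residues | packed into 32-bit codes; `k · bits ≤ 32` enforced (max 16 for DNA, 6 for protein) |
| `minIdentity` | 0.75 | fraction | accept threshold on alignment identity |
| `maxAccepts` | 1 | hits | per-query accept budget |
| `maxRejects` | 8 | candidates | per-query reject budget |
| `strand` | both (DNA), plus (protein) | — | shared budgets across strands |
| DNA scoring | +2 / −3, gap 5 + 2·L | half-bit-free integers | BLASTN-style |
| protein scoring | BLOSUM62, gap 11 + 1·L | half bits | NCBI-distributed matrix, shipped as text |
| `xdrop` | 16 (DNA), 32 (protein) | score units | ungapped extension stop |
| `bandRadius` | 16 | diagonals | auto-widened to the segment length difference |

The defaults `minIdentity = 0.75`, `maxAccepts = 1`, `maxRejects = 8`
make the bare command line reproduce the standard family-recovery
benchmark protocol. The DNA match/mismatch/gap values and the X-drop
and band parameters are this package's declared defaults (BLASTN and
BLAST+ conventions); they are not dictated by the heuristic itself and
are all user-settable.

Ambiguity handling: IUPAC codes (DNA) and B/Z/J/X/U/O (protein) are
accepted in input, but any k-length window containing one is mapped to
the AmbiguousKmer sentinel and excluded from indexing, U counting, and
seeding on both the database and the query side (symmetric by choice;
storing expanded ambiguous words would grow exponentially). At
alignment time an ambiguous DNA residue scores as the worst mismatch;
protein ambiguity codes use their BLOSUM62 rows, with J/U/O falling
back to the X row. The shipped BLOSUM62 is the NCBI BLAST-distributed
file; its canonical 20×20 block is the universal matrix, while B/Z/X
rows differ slightly between historical distributions — the NCBI
variant is used here.

## Numerical and tie-break choices

* **Packing.** Residue codes are fixed as A=0, C=1, G=2, T=3 and amino
  acids 0–19 in alphabetical one-letter order, big-endian within the
  32-bit word. Only the widths matter algorithmically; the assignments
  are frozen so that codes are stable across sessions.
* **Candidate order.** U descending, then ascending database position,
  then plus strand before minus. This makes the whole search
  deterministic; rerunning any search yields a byte-identical hit
  table.
* **U semantics.** Presence, not multiplicity: a k-mer occurring five
  times in both sequences contributes 1 to U. Postings store no
  positions; seed positions are recomputed per candidate pair, keeping
  index memory linear.
* **Extension.** The X-drop loop updates its best endpoint only on
  strict improvement, so the shortest best-scoring extension is
  returned; the HSP never shrinks below the seed.
* **Chaining ties.** Higher score first, then smaller query start,
  then smaller target start. Chaining is greedy exactly as stated —
  *not* optimal DP chaining — and the conformance oracle in the tests
  implements the same rule independently.
* **Banded DP.** Global affine-gap (Gotoh) recurrences restricted to
  the band; the traceback prefers match over insertion over deletion
  on exact score ties. Degenerate inputs are forced paths: an empty
  query segment against an m-residue target segment is `mD` with score
  −(open + m·extend); two empty segments are an empty bridge of score
  0. With a band radius at least the longer segment length the result
  provably equals unrestricted global alignment, which is how the DP
  is validated.
* **HSP dedup.** Seeds whose extensions land on identical intervals
  are collapsed before chaining.
* **No-seed candidates.** A candidate reached through shared k-mers
  can still fail to seed (ambiguity edge cases); it counts as a
  reject.
* **Queries shorter than k** produce no candidates and a warning, not
  an error.

## The synthetic benchmark

`generateFamilies()` emulates a family-recovery protocol: each family
is grown from one uniform random DNA root, and each member is derived
independently by per-residue substitution (to a different base),
single-residue insertion and deletion, and low-rate N injection. The
defaults — 200 families × 4 members, roots 150–300 nt, 10%
substitutions, 1% indels (0.5% + 0.5%), 0.2% N — define the package's
standard validation conditions; one member per family becomes a query
(`splitBenchmark()`), the rest form the database, and
`scoreAccuracy()` counts queries whose *first accepted hit* is in
their own family.

What the generator does and does not emulate: it reproduces the
*structure* of a family-recovery benchmark (common ancestry, controlled
divergence, disjoint query/database split) but not the biology of real
sequence families — no covariance or secondary-structure constraints,
no length-distributed indels, no compositional bias, no taxonomic
signal. Passing the benchmark therefore demonstrates that the engine
recovers relatives at the stated divergence under an identity
threshold; it does not certify accuracy numbers on any real database,
where divergence is heterogeneous and families overlap in sequence
space.

Determinism: all generator randomness derives from the single spec
seed, and the caller's RNG state is saved and restored, so fixtures are
pure functions of their spec.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at these scales,
chosen to exercise every code path at desk scale: 500 random pairs
(≤ 200 residues, both alphabets) for exact score agreement between the
banded aligner under a full-coverage band and an independent
full-matrix affine DP oracle; 200 query/database combinations for
exact U agreement against brute-force k-mer set intersection; a
1,000-sequence self-search (100% self-recovery at identity 1.0
expected); the 200-family benchmark above (top-1 family accuracy
≥ 0.95 asserted, with byte-identical repeat runs); and 200 random HSP
sets for greedy-chaining conformance. The per-query alignment count is
instrumented and asserted to never exceed `maxAccepts + maxRejects`.

## Known limitations

* No E-values, bit scores, or composition-based statistics: the accept
  statistic is alignment identity only, so very short chance seeds in
  unrelated sequences can be reported as short perfect-identity hits
  if they survive the identity threshold. Filter on
  `alignment_length` downstream if that matters for your use.
* Greedy chaining can differ from optimal chaining on adversarial HSP
  configurations; this is by construction.
* The k-mer filter bounds sensitivity: pairs conserving no exact
  k-mer are never examined.
* A `KmerIndex` holds native memory behind an external pointer and
  does not survive serialization; rebuild it per session (indexing is
  fast at desk scale).
* Translated searches, masking, and multi-file databases are out of
  scope.
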