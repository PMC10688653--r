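Package: kblast
Title: Embeddable BLAST-Like Sequence Similarity Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A BLAST-like local similarity search for DNA, RNA, and amino
    acid sequences, designed to be embedded in R analyses rather than
    shelled out to. Database sequences are indexed in k-mer lookup tables;
    candidates are ranked by the number of unique k-mers (U) shared with
    the query and examined in decreasing order of U under configurable
    accept and reject budgets. Each candidate is aligned by seed-and-extend
    discovery of high-scoring segment pairs, greedy chaining, and banded
    affine-gap dynamic programming over inter-segment gaps; hits are
    thresholded on alignment identity. Includes FASTA input, BLAST-style
    tabular output with strand and CIGAR columns, BLOSUM62 protein scoring,
    a command-line front end, and a deterministic synthetic family
    benchmark generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Software
RoxygenNote: 7.3.3
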