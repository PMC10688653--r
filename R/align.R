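# Pairwise alignment: seeds, X-drop extension, greedy chaining, banded DP.

.as_residues <- function(x) {
  if (is(x, "SeqSet")) {
    stopifnot(length(x) == 1L)
    x@seq
  } else {
    as.character(x)
  }
}

#' Find exact k-mer seed matches between two sequences
#'
#' Reports every pair of identical, ambiguity-free length-k windows,
#' with runs of diagonal-adjacent (or overlapping) matches merged into
#' maximal seeds. Deterministic order: by diagonal (`tpos - qpos`), then
#' query position.
#'
#' @param query,target Residue strings or length-1 [SeqSet-class]
#'   objects over one alphabet.
#' @param k Seed k-mer size (default: the alphabet's).
#' @param alphabet An [Alphabet-class] or its name.
#' @return Data frame with 0-based columns `qpos`, `tpos`, and `length`
#'   (>= k).
#' @export
findSeeds <- function(query, target, k = NULL, alphabet = "dna") {
  if (is(query, "SeqSet")) alphabet <- query@alphabet
  alphabet <- getAlphabet(alphabet)
  if (is.null(k)) k <- alphabet@defaultK
  .cpp_find_seeds(.as_residues(query), .as_residues(target),
                  as.integer(k), alphabet@name)
}

#' Extend a seed into an ungapped HSP by X-drop
#'
#' Extends the exact-match seed left and right without gaps; extension
#' on a side stops once the running score falls more than `xdrop` below
#' the best score seen on that side, and the HSP is trimmed back to the
#' best-scoring endpoints. The returned segment always contains the seed
#' and scores at least as much as the bare seed window.
#'
#' @param query,target Residue strings or length-1 [SeqSet-class]s.
#' @param qpos,tpos,length Seed coordinates as from [findSeeds()]
#'   (0-based).
#' @param alphabet An [Alphabet-class] or its name (supplies scoring).
#' @param xdrop X-drop threshold (default: the alphabet's).
#' @return List with 0-based half-open `qs`, `qe`, `ts`, `te` and
#'   integer `score`.
#' @export
extendSeed <- function(query, target, qpos, tpos, length,
                       alphabet = "dna", xdrop = NULL) {
  if (is(query, "SeqSet")) alphabet <- query@alphabet
  alphabet <- getAlphabet(alphabet)
  if (is.null(xdrop)) xdrop <- alphabet@xdrop
  .cpp_extend_seed(.as_residues(query), .as_residues(target),
                   as.integer(qpos), as.integer(tpos), as.integer(length),
                   alphabet@scoreMatrix, rownames(alphabet@scoreMatrix),
                   alphabet@gapOpen, alphabet@gapExtend, as.integer(xdrop))
}

#' Greedily chain HSPs
#'
#' Selects HSPs by the greedy rule: take the highest-scoring HSP, then
#' repeatedly add the highest-scoring remaining HSP that is collinear
#' with and non-overlapping (in both query and target coordinates) with
#' every HSP selected so far, until none can be added. Ties break to the
#' smaller query start, then smaller target start. Note this is the
#' greedy rule, not optimal chaining.
#'
#' @param hsps Data frame with 0-based half-open columns `qs`, `qe`,
#'   `ts`, `te` and integer `score` (one query-target pair).
#' @return The selected rows of `hsps`, sorted by query coordinate.
#' @export
chainHsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(hsps)
  sel <- .cpp_chain_hsps(as.integer(hsps$qs), as.integer(hsps$qe),
                         as.integer(hsps$ts), as.integer(hsps$te),
                         as.integer(hsps$score))
  hsps[sel, , drop = FALSE]
}

#' Banded global affine-gap alignment of two segments
#'
#' End-to-end (Needleman-Wunsch-Gotoh) alignment restricted to the
#' diagonal band `|j - i| <= bandRadius` around the main diagonal
#' shifted for the length difference; the radius is auto-widened to at
#' least the length difference so a path always exists. A gap run of
#' length L costs `gapOpen + L * gapExtend`. Equals unrestricted global
#' alignment whenever the optimal path stays inside the band — in
#' particular whenever `bandRadius >= max(nchar(query), nchar(target))`.
#' Used by [alignPair()] to close the gaps between chained HSPs; either
#' segment may be empty (a pure insertion/deletion bridge).
#'
#' @param query,target Residue strings (possibly empty) or length-1
#'   [SeqSet-class]s.
#' @param alphabet An [Alphabet-class] or its name (supplies scoring).
#' @param bandRadius Band half-width (default 16).
#' @return List with `cigar` (text; M = column, I = query-only,
#'   D = target-only) and integer `score`.
#' @export
bandedAlign <- function(query, target, alphabet = "dna", bandRadius = 16L) {
  if (is(query, "SeqSet")) alphabet <- query@alphabet
  alphabet <- getAlphabet(alphabet)
  .cpp_banded_align(.as_residues(query), .as_residues(target),
                    alphabet@scoreMatrix, rownames(alphabet@scoreMatrix),
                    alphabet@gapOpen, alphabet@gapExtend,
                    as.integer(bandRadius))
}

#' Align a query-target pair through the full heuristic pipeline
#'
#' Runs seed finding, X-drop extension (deduplicating HSPs with
#' identical intervals), greedy chaining, and banded DP over the gaps
#' between consecutive chained HSPs. The alignment spans from the first
#' chained HSP's start to the last one's end; terminal unaligned
#' overhangs are excluded from the alignment and from identity. Identity
#' is matching columns divided by all alignment columns, gap columns
#' included.
#'
#' @param query,target Residue strings or length-1 [SeqSet-class]s.
#' @param alphabet An [Alphabet-class] or its name.
#' @param k Seed k-mer size (default: the alphabet's).
#' @param xdrop X-drop threshold (default: the alphabet's).
#' @param bandRadius Band half-width for gap closing (default 16).
#' @param extendedCigar Emit `=`/`X` columns instead of `M`.
#' @return `NULL` when the pair has no seeds; otherwise a list with
#'   0-based half-open `qs`, `qe`, `ts`, `te`, integer `score`,
#'   `matches`, `length` (total columns), `identity`
#'   (= matches / length), and `cigar`.
#' @examples
#' a <- alignPair(strrep("ACGT", 10), strrep("ACGT", 10), alphabet = "dna")
#' a$identity  # 1
#' @export
alignPair <- function(query, target, alphabet = "dna", k = NULL,
                      xdrop = NULL, bandRadius = 16L,
                      extendedCigar = FALSE) {
  if (is(query, "SeqSet")) alphabet <- query@alphabet
  alphabet <- getAlphabet(alphabet)
  if (is.null(k)) k <- alphabet@defaultK
  if (is.null(xdrop)) xdrop <- alphabet@xdrop
  res <- .cpp_align_pair(.as_residues(query), .as_residues(target),
                         as.integer(k), alphabet@name,
                         alphabet@scoreMatrix,
                         rownames(alphabet@scoreMatrix),
                         alphabet@gapOpen, alphabet@gapExtend,
                         as.integer(xdrop), as.integer(bandRadius),
                         isTRUE(extendedCigar))
  if (!res$found) return(NULL)
  res$found <- NULL
  res$identity <- res$matches / res$length
  res
}

#' Identity of an alignment
#'
#' Matching columns divided by total alignment columns (gap columns
#' included), as a fraction in `[0, 1]`.
#'
#' @param alignment Result of [alignPair()] (or any list with `matches`
#'   and `length` elements).
#' @return Numeric scalar.
#' @export
identityOf <- function(alignment) {
  if (is.null(alignment)) return(NA_real_)
  alignment$matches / alignment$length
}
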