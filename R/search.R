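# The accept/reject search driver.

.STRANDS <- c("plus", "minus", "both")

.empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gap_openings = integer(),
             q.start = integer(), q.end = integer(),
             t.start = integer(), t.end = integer(),
             strand = character(), cigar = character(),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Search queries against a prebuilt k-mer index
#'
#' The core accept/reject loop. For each query, candidate database
#' sequences are ranked by the number of unique shared k-mers U (see
#' [countShared()]) and aligned in decreasing-U order with
#' [alignPair()]. A candidate whose identity reaches `minIdentity` is
#' accepted as a hit; otherwise (including candidates yielding no
#' alignment) it counts as a reject. The per-query loop stops once
#' `maxAccepts` hits are found, `maxRejects` candidates are rejected, or
#' candidates run out — so at most `maxAccepts + maxRejects` alignments
#' are ever computed per query.
#'
#' For DNA, `strand` chooses whether the query is compared as given
#' (`"plus"`), reverse-complemented (`"minus"`), or both. With
#' `"both"`, the two candidate lists are merged into one decreasing-U
#' ranking (ties: ascending database position, plus before minus) and
#' the accept/reject budgets are shared across strands. Minus-strand hit
#' coordinates refer to the original, unreversed query with
#' `q.start <= q.end` and strand `"-"`.
#'
#' @param query A [SeqSet-class] of query sequences.
#' @param index A [KmerIndex-class] built with [buildIndex()].
#' @param minIdentity Minimum hit identity, fraction in `(0, 1]`
#'   (default 0.75).
#' @param maxAccepts,maxRejects Per-query accept / reject budgets
#'   (defaults 1 and 8).
#' @param strand `"both"` (DNA default), `"plus"` (protein forced), or
#'   `"minus"`.
#' @param xdrop,bandRadius Alignment tuning; see [alignPair()].
#' @param stats Also return per-query alignment counts.
#' @return A hit data frame in acceptance order (columns as in
#'   [writeHits()], identity as a fraction); with `stats = TRUE`, a list
#'   with elements `hits` and `nAligned` (named integer vector).
#' @seealso [blastSearch()] for the one-call front end.
#' @export
searchIndex <- function(query, index, minIdentity = 0.75,
                        maxAccepts = 1L, maxRejects = 8L,
                        strand = NULL, xdrop = NULL, bandRadius = 16L,
                        stats = FALSE) {
  stopifnot(is(query, "SeqSet"), is(index, "KmerIndex"))
  alphabet <- index@alphabet
  if (query@alphabet@name != alphabet@name)
    stop("query and index alphabets differ")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must lie in (0, 1]")
  if (maxAccepts < 1L || maxRejects < 1L)
    stop("maxAccepts and maxRejects must be >= 1")
  if (is.null(strand)) strand <- if (alphabet@name == "dna") "both" else "plus"
  strand <- match.arg(strand, .STRANDS)
  if (alphabet@name == "protein" && strand != "plus")
    stop("strand '", strand, "' is undefined for the protein alphabet")
  if (is.null(xdrop)) xdrop <- alphabet@xdrop
  mode <- match(strand, .STRANDS) - 1L  # 0 plus, 1 minus, 2 both
  rc <- if (mode != 0L) .revcomp_chr(query@seq) else character(length(query))
  short <- nchar(query@seq) < index@k
  if (any(short))
    warning(sprintf("%d quer%s shorter than k = %d cannot seed any match",
                    sum(short), if (sum(short) == 1) "y is" else "ies are",
                    index@k))
  res <- .cpp_search(index@ptr, query@seq, rc, mode,
                     alphabet@scoreMatrix, rownames(alphabet@scoreMatrix),
                     alphabet@gapOpen, alphabet@gapExtend,
                     as.integer(xdrop), as.integer(bandRadius),
                     minIdentity, as.integer(maxAccepts),
                     as.integer(maxRejects))
  hits <- data.frame(
    query_id = query@id[res$query + 1L],
    target_id = index@ids[res$target + 1L],
    identity = res$identity,
    alignment_length = res$alen,
    mismatches = res$mismatches,
    gap_openings = res$gap_openings,
    q.start = res$qstart, q.end = res$qend,
    t.start = res$tstart, t.end = res$tend,
    strand = if (alphabet@name == "protein")
      rep("n/a", length(res$strand)) else res$strand,
    cigar = res$cigar,
    stringsAsFactors = FALSE, check.names = FALSE)
  if (stats)
    list(hits = hits, nAligned = stats::setNames(res$n_aligned, query@id))
  else hits
}

#' BLAST-like search of queries against a database
#'
#' The one-call entry point: reads or accepts the query and database
#' sequence sets, builds the k-mer index over the database once, runs
#' the accept/reject search for every query in order (see
#' [searchIndex()]), and returns — and optionally writes — the
#' concatenated hit table. Fully deterministic given inputs and
#' parameters. The defaults reproduce the standard protocol: report up
#' to one hit of at least 75% identity, giving up after 8 rejected
#' candidates.
#'
#' @param query,db [SeqSet-class] objects or FASTA file paths.
#' @param maxAccepts,maxRejects Per-query accept / reject budgets
#'   (defaults 1 and 8).
#' @param minIdentity Minimum hit identity, fraction in `(0, 1]`
#'   (default 0.75).
#' @param alphabet `"auto"` (default), `"dna"`, `"protein"`, or an
#'   [Alphabet-class]; applied to both sequence sets when they are read
#'   from paths.
#' @param strand `"both"` (DNA default), `"plus"`, or `"minus"`.
#' @param k k-mer size (default: the alphabet's).
#' @param output Optional path; when given, the hit table is also
#'   written there via [writeHits()].
#' @param dialect Output dialect for `output`, `"tsv"` or `"csv"`.
#' @param ... Further tuning passed to [searchIndex()] (`xdrop`,
#'   `bandRadius`, `stats`).
#' @return A hit data frame (see [searchIndex()]).
#' @examples
#' db <- SeqSet(c(strrep("ACGT", 30), strrep("GGCA", 30)),
#'              id = c("t1", "t2"))
#' blastSearch(db[1], db)[, 1:4]
#' @export
blastSearch <- function(query, db, maxAccepts = 1L, maxRejects = 8L,
                        minIdentity = 0.75, alphabet = "auto",
                        strand = NULL, k = NULL, output = NULL,
                        dialect = c("tsv", "csv"), ...) {
  if (is.character(db)) db <- readFasta(db, alphabet = alphabet)
  if (is.character(query))
    query <- readFasta(query, alphabet = db@alphabet)
  index <- buildIndex(db, k = k)
  res <- searchIndex(query, index, minIdentity = minIdentity,
                     maxAccepts = maxAccepts, maxRejects = maxRejects,
                     strand = strand, ...)
  if (!is.null(output)) {
    hits <- if (is.data.frame(res)) res else res$hits
    writeHits(hits, output, dialect = match.arg(dialect))
  }
  res
}
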