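# k-mer encoding, database indexing, and U counting.

#' The ambiguous k-mer sentinel
#'
#' Value returned by [encodeKmer()] for any window containing at least
#' one ambiguous residue. Such windows have no binary code: they are
#' excluded from the database index and never act as seeds.
#' @export
AmbiguousKmer <- NA_real_

#' Encode one k-mer window as a 32-bit packed code
#'
#' Packs a length-k window big-endian, `bitsPerSymbol` bits per residue
#' (DNA: A=0, C=1, G=2, T=3; protein: canonical residues 0..19 in
#' alphabetical order, 5 bits). Windows containing an ambiguous residue
#' return [AmbiguousKmer].
#'
#' @param window A single residue string of length k.
#' @param alphabet An [Alphabet-class] or its name.
#' @return Numeric scalar code in `[0, 2^(bits*k))`, or [AmbiguousKmer].
#' @examples
#' encodeKmer("ACGT", "dna")  # 27
#' encodeKmer("ACNT", "dna")  # AmbiguousKmer (NA)
#' @export
encodeKmer <- function(window, alphabet = "dna") {
  alphabet <- getAlphabet(alphabet)
  k <- nchar(window)
  res <- .cpp_enumerate_kmers(window, k, alphabet@name)
  if (length(res$code) == 0L) AmbiguousKmer else res$code[1]
}

#' Enumerate the valid k-mer windows of a sequence
#'
#' One entry per window position `0 .. len-k` whose window is free of
#' ambiguous residues; windows overlapping an ambiguity are omitted
#' entirely (they carry the [AmbiguousKmer] sentinel and are never
#' indexed). Returns an empty frame when the sequence is shorter than k.
#'
#' @param seq A residue string (normalized) or a length-1 [SeqSet-class].
#' @param k k-mer size; `k * bitsPerSymbol` must be at most 32.
#' @param alphabet An [Alphabet-class] or its name (ignored when `seq`
#'   is a `SeqSet`).
#' @return Data frame with columns `pos` (0-based offset) and `code`.
#' @export
enumerateKmers <- function(seq, k = NULL, alphabet = "dna") {
  if (is(seq, "SeqSet")) {
    stopifnot(length(seq) == 1L)
    alphabet <- seq@alphabet
    seq <- seq@seq
  }
  alphabet <- getAlphabet(alphabet)
  if (is.null(k)) k <- alphabet@defaultK
  res <- .cpp_enumerate_kmers(seq, as.integer(k), alphabet@name)
  data.frame(pos = res$pos, code = res$code)
}

#' Build the k-mer lookup-table index over a database
#'
#' Stores, for every canonical k-mer code occurring in the database, the
#' ids of the sequences containing it at least once (presence only).
#' Construction is a pure function of the sequences and k; ids are
#' assigned in input order.
#'
#' @param db A [SeqSet-class] of database sequences.
#' @param k k-mer size (default: the alphabet's, 8 for DNA, 5 for
#'   protein); `k * bitsPerSymbol` must be at most 32.
#' @return A [KmerIndex-class].
#' @seealso [countShared()], [searchIndex()]
#' @export
buildIndex <- function(db, k = NULL) {
  stopifnot(is(db, "SeqSet"))
  alphabet <- db@alphabet
  if (is.null(k)) k <- alphabet@defaultK
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k * alphabet@bitsPerSymbol > 32L)
    stop(sprintf("k = %d needs %d bits/symbol * %d = %d bits; max is 32",
                 k, alphabet@bitsPerSymbol, k, k * alphabet@bitsPerSymbol))
  new("KmerIndex", ptr = .cpp_build_index(db@seq, k, alphabet@name),
      k = k, alphabet = alphabet, ids = db@id)
}

setMethod("show", "KmerIndex", function(object) {
  info <- .cpp_index_info(object@ptr)
  cat(sprintf(
    "KmerIndex: %d %s sequences, k=%d, %.0f distinct k-mers indexed\n",
    info$n_sequences, info$alphabet, info$k, info$n_kmers))
})

#' Dump index postings (small indexes; tests and inspection)
#'
#' @param index A [KmerIndex-class].
#' @return Data-frame-free list: `code` (numeric vector of k-mer codes,
#'   ascending) and `ids` (parallel list of character vectors of database
#'   sequence ids).
#' @export
indexPostings <- function(index) {
  stopifnot(is(index, "KmerIndex"))
  d <- .cpp_index_dump(index@ptr)
  list(code = d$code, ids = lapply(d$ids, function(i) index@ids[i + 1L]))
}

#' Count unique shared k-mers (U) against every database sequence
#'
#' For each database sequence t, U(t) is the number of *distinct* k-mers
#' occurring in both the query and t (repeats within a sequence count
#' once). The returned candidate list is sorted by U strictly
#' non-increasing, ties broken by ascending database position; targets
#' with U = 0 are excluded. This is the candidate ordering the search
#' driver walks.
#'
#' @param query A residue string or length-1 [SeqSet-class].
#' @param index A [KmerIndex-class].
#' @return Data frame with columns `target` (1-based database position),
#'   `target_id`, and `u`.
#' @export
countShared <- function(query, index) {
  stopifnot(is(index, "KmerIndex"))
  if (is(query, "SeqSet")) {
    stopifnot(length(query) == 1L)
    query <- query@seq
  }
  res <- .cpp_count_shared(index@ptr, query)
  data.frame(target = res$target + 1L,
             target_id = index@ids[res$target + 1L],
             u = res$u, stringsAsFactors = FALSE)
}
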