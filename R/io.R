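# FASTA input/output and the tabular hit format.

.HIT_COLUMNS <- c("query_id", "target_id", "identity", "alignment_length",
                  "mismatches", "gap_openings", "q.start", "q.end",
                  "t.start", "t.end", "strand", "cigar")

#' Detect the alphabet of raw sequences
#'
#' A sequence set is called DNA when at least 95% of the residues across
#' (up to) the first 100 sequences are A, C, G, T, U, or N; otherwise
#' protein. Intended as a convenience default — pass the alphabet
#' explicitly when you know it.
#'
#' @param seq Character vector of residue strings.
#' @return `"dna"` or `"protein"`.
#' @export
detectAlphabet <- function(seq) {
  seq <- toupper(head(seq, 100L))
  all_chars <- strsplit(paste(seq, collapse = ""), "", fixed = TRUE)[[1]]
  if (length(all_chars) == 0L) stop("cannot detect alphabet: no residues")
  frac <- mean(all_chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.95) "dna" else "protein"
}

#' Read sequences from a FASTA file
#'
#' Parses (possibly multi-line) FASTA into a [SeqSet-class]. The first
#' whitespace-delimited token of each `>` header is the identifier, the
#' remainder the description. Residues are normalized and validated
#' against the alphabet; records with empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @param alphabet An [Alphabet-class], `"dna"`, `"protein"`, or
#'   `"auto"` (default) to detect from the residues.
#' @return A [SeqSet-class] in file order.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(errorCondition(
      sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
      class = c("kblast_malformed_fasta", "error"))))
  if (length(x) == 0L)
    stop(errorCondition(sprintf("no FASTA records in '%s'", path),
                        class = c("kblast_malformed_fasta", "error")))
  if (any(Biostrings::width(x) == 0L))
    stop(errorCondition(
      sprintf("empty sequence record in '%s' (%s)", path,
              names(x)[Biostrings::width(x) == 0L][1]),
      class = c("kblast_malformed_fasta", "error")))
  header <- names(x)
  id <- sub("\\s.*$", "", header)
  desc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
  if (any(!nzchar(id)))
    stop(errorCondition(sprintf("empty FASTA header in '%s'", path),
                        class = c("kblast_malformed_fasta", "error")))
  SeqSet(as.character(x), id = id, desc = desc, alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param x A [SeqSet-class].
#' @param path Output path.
#' @param width Line width for residue wrapping.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path, width = 70L) {
  stopifnot(is(x, "SeqSet"))
  b <- Biostrings::BStringSet(x@seq)
  names(b) <- ifelse(nzchar(x@desc), paste(x@id, x@desc), x@id)
  Biostrings::writeXStringSet(b, path, width = width)
  invisible(path)
}

#' Write a hit table
#'
#' Writes hits in a BLAST outfmt-6-like layout with two extra trailing
#' columns (strand, CIGAR): query_id, target_id, identity (percentage,
#' one decimal), alignment_length, mismatches, gap_openings, q.start,
#' q.end, t.start, t.end, strand, cigar. A header row is always emitted;
#' output is byte-identical for identical inputs.
#'
#' @param hits Hit data frame as returned by [blastSearch()] (identity
#'   stored as a fraction in `[0, 1]`).
#' @param path Output path or connection.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `path`.
#' @seealso [readHits()]
#' @export
writeHits <- function(hits, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(all(.HIT_COLUMNS %in% names(hits)))
  out <- hits[, .HIT_COLUMNS, drop = FALSE]
  out$identity <- sprintf("%.1f", 100 * out$identity)
  write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a hit table written by [writeHits()]
#'
#' The inverse of [writeHits()] at the printed precision: identity
#' percentages (one decimal) are converted back to fractions.
#'
#' @param path Path to a hit table.
#' @param dialect `"tsv"`, `"csv"`, or `"auto"` (default; sniffed from
#'   the header line).
#' @return Hit data frame with the standard columns.
#' @export
readHits <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("\t", first)) "tsv" else "csv"
  }
  sep <- if (dialect == "tsv") "\t" else ","
  first <- readLines(path, n = 1L)
  if (!identical(strsplit(first, sep, fixed = TRUE)[[1]], .HIT_COLUMNS))
    stop(errorCondition(
      sprintf("'%s' does not look like a kblast hit table", path),
      class = c("kblast_malformed_hit_table", "error")))
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               colClasses = c("character", "character", "numeric",
                              "integer", "integer", "integer", "integer",
                              "integer", "integer", "integer",
                              "character", "character"),
               stringsAsFactors = FALSE),
    error = function(e) stop(errorCondition(
      sprintf("malformed hit table '%s': %s", path, conditionMessage(e)),
      class = c("kblast_malformed_hit_table", "error"))))
  if (any(is.na(df$`q.start`)))
    stop(errorCondition(sprintf("malformed hit table '%s'", path),
                        class = c("kblast_malformed_hit_table", "error")))
  df$identity <- df$identity / 100
  df
}
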