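# Alphabet construction and residue-level operations.

.DNA_SYMBOLS <- c("A", "C", "G", "T")
.DNA_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
# canonical amino acids in alphabetical one-letter order (bit codes 0..19)
.AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_AMBIG <- c("B", "Z", "J", "X", "U", "O")

# IUPAC complement table (canonical + ambiguity codes)
.DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Read a substitution matrix in NCBI text format
#'
#' Parses a scoring matrix laid out the way NCBI BLAST distributes them:
#' `#` comment lines, a header row of single-letter column labels, then
#' one labelled row of integers per residue.
#'
#' @param path Path to the matrix file.
#' @return Symmetric integer matrix with residue dimnames.
#' @seealso [writeScoreMatrix()], [blosum62()]
#' @export
readScoreMatrix <- function(path) {
  m <- as.matrix(read.table(path, check.names = FALSE, comment.char = "#"))
  colnames(m) <- rownames(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a substitution matrix in NCBI text format
#'
#' @param mat Integer matrix with single-character dimnames.
#' @param path Output path or connection.
#' @return Invisibly, `path`.
#' @export
writeScoreMatrix <- function(mat, path) {
  letters <- colnames(mat)
  lines <- c(
    paste0("   ", paste(sprintf("%2s", letters), collapse = " ")),
    vapply(seq_len(nrow(mat)), function(i) {
      paste0(rownames(mat)[i], " ",
             paste(sprintf("%2d", mat[i, ]), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' The packaged BLOSUM62 substitution matrix
#'
#' The NCBI BLAST-distributed BLOSUM62 matrix (half-bit units), including
#' the B/Z/X ambiguity rows and the `*` column, as shipped with the
#' package in NCBI text format.
#'
#' @return Symmetric integer matrix (24 x 24).
#' @examples
#' blosum62()["W", "W"]  # 11
#' @export
blosum62 <- function() {
  readScoreMatrix(system.file("extdata", "BLOSUM62.txt",
                              package = "kblast", mustWork = TRUE))
}

#' DNA/RNA alphabet
#'
#' Canonical symbols A, C, G, T packed 2 bits per residue (A=0, C=1, G=2,
#' T=3), default k = 8, with the IUPAC ambiguity codes accepted in input
#' but excluded from k-mer indexing. RNA is handled by normalizing U to T.
#' Scoring is BLASTN-style match/mismatch; any pair involving an ambiguity
#' code scores as a mismatch.
#'
#' @param match,mismatch Substitution scores for identical / differing
#'   canonical nucleotides.
#' @param gapOpen,gapExtend Affine gap penalties (positive, subtracted); a
#'   gap run of length L costs `gapOpen + L * gapExtend`.
#' @param xdrop X-drop threshold for ungapped seed extension.
#' @return An [Alphabet-class] object.
#' @examples
#' dna <- dnaAlphabet()
#' scorePair("A", "A", dna)  #  2
#' scorePair("A", "G", dna)  # -3
#' @export
dnaAlphabet <- function(match = 2L, mismatch = -3L,
                        gapOpen = 5L, gapExtend = 2L, xdrop = 16L) {
  letters <- c(.DNA_SYMBOLS, .DNA_AMBIG)
  sm <- matrix(as.integer(mismatch), length(letters), length(letters),
               dimnames = list(letters, letters))
  diag(sm)[.DNA_SYMBOLS] <- as.integer(match)
  new("Alphabet",
      name = "dna", symbols = .DNA_SYMBOLS, bitsPerSymbol = 2L,
      defaultK = 8L, ambiguity = .DNA_AMBIG, scoreMatrix = sm,
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      xdrop = as.integer(xdrop))
}

#' Protein alphabet
#'
#' The 20 canonical amino acids packed 5 bits per residue (coded 0..19 in
#' alphabetical one-letter order), default k = 5, scored with the
#' packaged BLOSUM62 matrix. Ambiguity codes B, Z, and X score by their
#' BLOSUM62 rows; J, U, and O (not present in the classic matrix) fall
#' back to the X row.
#'
#' @param gapOpen,gapExtend Affine gap penalties (BLAST+ protein
#'   defaults 11 / 1).
#' @param xdrop X-drop threshold for ungapped seed extension.
#' @return An [Alphabet-class] object.
#' @examples
#' aa <- proteinAlphabet()
#' scorePair("W", "W", aa)  # 11
#' @export
proteinAlphabet <- function(gapOpen = 11L, gapExtend = 1L, xdrop = 32L) {
  b62 <- blosum62()
  letters <- c(.AA_SYMBOLS, .AA_AMBIG)
  # map letters missing from the classic matrix onto the X row
  src <- c(stats::setNames(.AA_SYMBOLS, .AA_SYMBOLS),
           c(B = "B", Z = "Z", X = "X", J = "X", U = "X", O = "X"))
  sm <- b62[src[letters], src[letters]]
  dimnames(sm) <- list(letters, letters)
  new("Alphabet",
      name = "protein", symbols = .AA_SYMBOLS, bitsPerSymbol = 5L,
      defaultK = 5L, ambiguity = .AA_AMBIG, scoreMatrix = sm,
      gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
      xdrop = as.integer(xdrop))
}

#' Look up an alphabet by name
#' @param alphabet An [Alphabet-class] object or one of `"dna"`,
#'   `"protein"`.
#' @return An [Alphabet-class] object.
#' @export
getAlphabet <- function(alphabet) {
  if (is(alphabet, "Alphabet")) return(alphabet)
  switch(match.arg(alphabet, c("dna", "protein")),
         dna = dnaAlphabet(), protein = proteinAlphabet())
}

#' @describeIn Alphabet-class the alphabet's name ("dna" or "protein")
#' @param x,object An `Alphabet`.
#' @export
alphabetName <- function(x) x@name

#' @describeIn Alphabet-class default k-mer size of the alphabet
#' @export
defaultK <- function(x) x@defaultK

#' @describeIn Alphabet-class the substitution matrix over
#'   `c(symbols, ambiguity)`
#' @export
scoreMatrix <- function(x) x@scoreMatrix

#' @describeIn Alphabet-class affine gap penalties as
#'   `c(open = , extend = )`
#' @export
gapPenalties <- function(x) c(open = x@gapOpen, extend = x@gapExtend)

setMethod("show", "Alphabet", function(object) {
  cat(sprintf("Alphabet '%s': %d symbols (%s), %d bits/symbol, k=%d\n",
              object@name, length(object@symbols),
              paste(head(object@symbols, 6), collapse = ""),
              object@bitsPerSymbol, object@defaultK))
  cat(sprintf("  ambiguity codes: %s\n",
              paste(object@ambiguity, collapse = "")))
  cat(sprintf("  gap open %d, gap extend %d, xdrop %d\n",
              object@gapOpen, object@gapExtend, object@xdrop))
})

#' Score one residue pair
#'
#' @param a,b Single residue characters (canonical or ambiguity codes).
#' @param alphabet An [Alphabet-class] or its name.
#' @return Integer substitution score.
#' @export
scorePair <- function(a, b, alphabet = dnaAlphabet()) {
  alphabet <- getAlphabet(alphabet)
  sm <- alphabet@scoreMatrix
  ok <- c(a, b) %in% rownames(sm)
  if (!all(ok))
    stop("residue not in alphabet: ", paste(c(a, b)[!ok], collapse = ", "))
  sm[a, b]
}

#' Normalize raw residue text against an alphabet
#'
#' Uppercases, strips whitespace, rewrites U to T for the DNA alphabet,
#' and rejects any character outside the alphabet's canonical symbols and
#' ambiguity codes, naming the offending character and its position.
#' Idempotent: normalizing already-normalized text is the identity.
#'
#' @param x Character vector of raw residue strings.
#' @param alphabet An [Alphabet-class] or its name.
#' @param id Optional identifiers used to label errors.
#' @return Character vector of normalized residue strings.
#' @export
normalizeResidues <- function(x, alphabet = dnaAlphabet(), id = NULL) {
  alphabet <- getAlphabet(alphabet)
  x <- toupper(gsub("[ \t\r\n]", "", x))
  if (alphabet@name == "dna") x <- gsub("U", "T", x, fixed = TRUE)
  valid <- c(alphabet@symbols, alphabet@ambiguity)
  bad <- regexpr(sprintf("[^%s]", paste(valid, collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    where <- if (is.null(id)) sprintf("sequence %d", i) else
      sprintf("sequence '%s'", id[i])
    stop(errorCondition(
      sprintf("invalid residue '%s' at position %d in %s (alphabet %s)",
              substr(x[i], bad[i], bad[i]), bad[i], where, alphabet@name),
      class = c("kblast_invalid_residue", "error")))
  }
  x
}

#' Reverse complement
#'
#' Reverse-complements DNA residues, complementing IUPAC ambiguity codes
#' by the standard table (N stays N, R pairs with Y, and so on). An
#' involution: applying it twice returns the original residues. Defined
#' for DNA only; protein input is an error.
#'
#' @param x A [SeqSet-class] over the DNA alphabet.
#' @return An object of the same class with reverse-complemented
#'   residues (ids and descriptions preserved).
#' @importFrom Biostrings reverseComplement
#' @examples
#' s <- SeqSet("AACN", id = "s1")
#' as.character(reverseComplement(s))  # "NGTT"
#' @export
setMethod("reverseComplement", "SeqSet", function(x, ...) {
  if (x@alphabet@name != "dna")
    stop("reverseComplement is defined for the dna alphabet only")
  initialize(x, seq = .revcomp_chr(x@seq))
})

.revcomp_chr <- function(x) {
  from <- paste(names(.DNA_COMPLEMENT), collapse = "")
  to <- paste(.DNA_COMPLEMENT, collapse = "")
  vapply(chartr(from, to, x), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
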