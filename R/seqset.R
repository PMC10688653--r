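# SeqSet construction and basic methods.

#' Construct a SeqSet
#'
#' Builds a [SeqSet-class] from residue strings, normalizing and
#' validating them against the alphabet (see [normalizeResidues()]).
#'
#' @param seq Character vector of residue strings.
#' @param id Character vector of identifiers (default `seq1`, `seq2`, ...).
#' @param desc Character vector of descriptions (default empty).
#' @param alphabet An [Alphabet-class], its name, or `"auto"` to detect
#'   DNA vs protein from the residues (see [detectAlphabet()]).
#' @return A [SeqSet-class].
#' @examples
#' s <- SeqSet(c("acgu", "GGCC"), id = c("a", "b"))
#' as.character(s)  # "ACGT" "GGCC"
#' @export
SeqSet <- function(seq, id = NULL, desc = NULL, alphabet = "auto") {
  seq <- as.character(seq)
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  if (is.null(desc)) desc <- rep("", length(seq))
  if (identical(alphabet, "auto")) alphabet <- detectAlphabet(seq)
  alphabet <- getAlphabet(alphabet)
  new("SeqSet", id = as.character(id), desc = as.character(desc),
      seq = normalizeResidues(seq, alphabet, id = id), alphabet = alphabet)
}

#' @describeIn SeqSet-class number of sequences
#' @param x A `SeqSet`.
#' @export
setMethod("length", "SeqSet", function(x) length(x@seq))

#' @describeIn SeqSet-class sequence identifiers
#' @export
setMethod("names", "SeqSet", function(x) x@id)

#' @describeIn SeqSet-class residue strings as a named character vector
#' @export
setMethod("as.character", "SeqSet", function(x)
  stats::setNames(x@seq, x@id))

#' @describeIn SeqSet-class subset by index, logical, or identifier
#' @param i Index vector.
#' @param j,...,drop Ignored (matrix-style arguments).
#' @export
setMethod("[", "SeqSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@id)
  initialize(x, id = x@id[i], desc = x@desc[i], seq = x@seq[i])
})

#' @describeIn SeqSet-class sequence lengths in residues
#' @export
seqWidths <- function(x) stats::setNames(nchar(x@seq), x@id)

#' @describeIn SeqSet-class sequence descriptions
#' @export
seqDescriptions <- function(x) stats::setNames(x@desc, x@id)

#' @describeIn SeqSet-class the alphabet of the set
#' @export
seqAlphabet <- function(x) x@alphabet

#' @describeIn SeqSet-class concatenate sets sharing one alphabet
#' @export
setMethod("c", "SeqSet", function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    stopifnot(is(y, "SeqSet"))
    if (y@alphabet@name != x@alphabet@name)
      stop("cannot concatenate SeqSets over different alphabets")
    x <- initialize(x, id = c(x@id, y@id), desc = c(x@desc, y@desc),
                    seq = c(x@seq, y@seq))
  }
  x
})

setMethod("show", "SeqSet", function(object) {
  n <- length(object)
  cat(sprintf("SeqSet of %d %s sequence%s\n", n, object@alphabet@name,
              if (n == 1) "" else "s"))
  if (n > 0) {
    w <- nchar(object@seq)
    cat(sprintf("  lengths %d..%d\n", min(w), max(w)))
    k <- min(n, 5L)
    for (i in seq_len(k)) {
      s <- object@seq[i]
      cat(sprintf("  %s  %s%s\n", object@id[i],
                  substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
    }
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})
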