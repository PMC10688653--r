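#' Alphabet: residue set, k-mer packing policy, and pairwise scoring
#'
#' An `Alphabet` bundles everything the search engine needs to know about a
#' sequence type: the canonical residue symbols, the ambiguity codes that
#' are tolerated in input but excluded from k-mer indexing, the number of
#' bits used to pack one residue into a 32-bit k-mer code, the default
#' k-mer size, and the pairwise scoring model (substitution matrix plus
#' affine gap penalties, with an X-drop threshold for ungapped extension).
#'
#' Two alphabets are provided: [dnaAlphabet()] (also used for RNA; U is
#' normalized to T on input) and [proteinAlphabet()] (BLOSUM62 scoring).
#' The class is ordinary S4, so further alphabets can be constructed
#' without touching the engine, provided `defaultK * bitsPerSymbol <= 32`.
#'
#' @slot name Single string, `"dna"` or `"protein"`.
#' @slot symbols Character vector of canonical residue characters.
#' @slot bitsPerSymbol Integer, bits used per residue in k-mer packing.
#' @slot defaultK Integer, default k-mer size.
#' @slot ambiguity Character vector of ambiguity codes accepted in input.
#' @slot scoreMatrix Symmetric integer matrix over
#'   `c(symbols, ambiguity)` giving the substitution score of each pair.
#' @slot gapOpen,gapExtend Non-negative integers; a gap run of length L
#'   costs `gapOpen + L * gapExtend` (subtracted from the score).
#' @slot xdrop Positive integer; default X-drop for ungapped extension.
#'
#' @seealso [dnaAlphabet()], [proteinAlphabet()], [scorePair()]
#' @export
setClass("Alphabet",
  representation(
    name = "character",
    symbols = "character",
    bitsPerSymbol = "integer",
    defaultK = "integer",
    ambiguity = "character",
    scoreMatrix = "matrix",
    gapOpen = "integer",
    gapExtend = "integer",
    xdrop = "integer"
  )
)

setValidity("Alphabet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !object@name %in% c("dna", "protein"))
    msg <- c(msg, "name must be 'dna' or 'protein'")
  if (2^object@bitsPerSymbol < length(object@symbols))
    msg <- c(msg, "2^bitsPerSymbol must cover the symbol set")
  if (object@defaultK * object@bitsPerSymbol > 32L)
    msg <- c(msg, "defaultK * bitsPerSymbol must be <= 32")
  letters <- c(object@symbols, object@ambiguity)
  sm <- object@scoreMatrix
  if (!identical(rownames(sm), letters) || !identical(colnames(sm), letters))
    msg <- c(msg, "scoreMatrix dimnames must equal c(symbols, ambiguity)")
  else if (!isSymmetric(unname(sm)))
    msg <- c(msg, "scoreMatrix must be symmetric")
  if (object@gapOpen < 0L || object@gapExtend < 0L)
    msg <- c(msg, "gap penalties must be non-negative")
  if (object@xdrop < 1L) msg <- c(msg, "xdrop must be positive")
  if (length(msg)) msg else TRUE
})

#' SeqSet: an ordered set of identified sequences over one alphabet
#'
#' The basic sequence container: parallel identifier, description, and
#' residue vectors, tagged with the [Alphabet-class] they are written in.
#' Residues are normalized at construction (uppercased, whitespace
#' stripped, U -> T for DNA) and validated: any character outside the
#' alphabet's canonical symbols and ambiguity codes is an error.
#'
#' @slot id Character vector of non-empty, unique-enough identifiers.
#' @slot desc Character vector of descriptions (may be empty strings).
#' @slot seq Character vector of normalized residue strings.
#' @slot alphabet The [Alphabet-class] of the residues.
#'
#' @seealso [SeqSet()], [readFasta()], [reverseComplement()]
#' @export
setClass("SeqSet",
  representation(
    id = "character",
    desc = "character",
    seq = "character",
    alphabet = "Alphabet"
  )
)

setValidity("SeqSet", function(object) {
  msg <- character()
  n <- length(object@seq)
  if (length(object@id) != n || length(object@desc) != n)
    msg <- c(msg, "id, desc and seq must have equal length")
  if (any(!nzchar(object@id)))
    msg <- c(msg, "sequence identifiers must be non-empty")
  if (any(!nzchar(object@seq)))
    msg <- c(msg, "empty sequences are not allowed")
  if (length(msg)) msg else TRUE
})

#' KmerIndex: k-mer lookup tables over a sequence database
#'
#' Postings from each canonical (ambiguity-free) k-mer code to the sorted
#' ids of the database sequences containing it at least once — presence,
#' not multiplicity, so shared-k-mer counts U are counts of *unique*
#' shared k-mers. Windows containing an ambiguous residue map to the
#' AmbiguousKmer sentinel and are excluded from the tables entirely.
#'
#' The postings live in native memory behind an external pointer and are
#' rebuilt with [buildIndex()]; a `KmerIndex` is therefore valid only
#' within the R session that built it (it does not survive `saveRDS()`).
#'
#' @slot ptr External pointer to the native index.
#' @slot k Integer k-mer size; `k * bitsPerSymbol <= 32`.
#' @slot alphabet The database [Alphabet-class].
#' @slot ids Character vector of database sequence identifiers, in input
#'   order (index ids are their positions).
#'
#' @seealso [buildIndex()], [countShared()], [searchIndex()]
#' @export
setClass("KmerIndex",
  representation(
    ptr = "externalptr",
    k = "integer",
    alphabet = "Alphabet",
    ids = "character"
  )
)

#' FamilySpec: parameters of the synthetic family benchmark generator
#'
#' Describes a synthetic sequence-family benchmark: a number of families,
#' each grown from an independent random DNA root, with members derived
#' from the root by per-residue substitution, insertion, and deletion
#' edits at the given rates, plus optional injection of ambiguous N
#' residues. All randomness is driven by the single `seed`, so two runs
#' with an equal spec produce identical sequences.
#'
#' @slot nFamilies Positive integer, number of families.
#' @slot membersPerFamily Integer >= 2, members per family.
#' @slot rootLengthRange Integer vector of length 2, inclusive range of
#'   root lengths (nt).
#' @slot subRate,insRate,delRate Per-residue edit rates in `[0, 1)`.
#' @slot ambigRate Per-residue probability of replacing a residue by N.
#' @slot seed Integer RNG seed.
#'
#' @seealso [familySpec()], [generateFamilies()], [splitBenchmark()]
#' @export
setClass("FamilySpec",
  representation(
    nFamilies = "integer",
    membersPerFamily = "integer",
    rootLengthRange = "integer",
    subRate = "numeric",
    insRate = "numeric",
    delRate = "numeric",
    ambigRate = "numeric",
    seed = "integer"
  )
)

setValidity("FamilySpec", function(object) {
  msg <- character()
  if (object@nFamilies < 1L) msg <- c(msg, "nFamilies must be >= 1")
  if (object@membersPerFamily < 2L)
    msg <- c(msg, "membersPerFamily must be >= 2")
  if (length(object@rootLengthRange) != 2L ||
      any(object@rootLengthRange < 1L) ||
      object@rootLengthRange[1] > object@rootLengthRange[2])
    msg <- c(msg, "rootLengthRange must be an increasing positive pair")
  rates <- c(object@subRate, object@insRate, object@delRate,
             object@ambigRate)
  if (any(rates < 0) || any(rates >= 1))
    msg <- c(msg, "rates must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
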