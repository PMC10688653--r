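# Deterministic synthetic family benchmark: sequence families grown from
# random roots by point mutation and single-residue indels, split into a
# query set (one member per family) and a reference database, emulating a
# family-recovery protocol at desk scale.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Construct a benchmark family specification
#'
#' Defaults describe the desk-scale benchmark used throughout the
#' package's validation: 200 families of 4 members grown from random
#' 150-300 nt roots, each member carrying ~10% substitutions and ~1%
#' indels (0.5% insertions + 0.5% deletions) relative to its root, plus
#' a trace of ambiguous N residues so ambiguity handling is exercised
#' end-to-end.
#'
#' @param nFamilies Number of families.
#' @param membersPerFamily Members per family (>= 2).
#' @param rootLengthRange Inclusive range of root lengths (nt).
#' @param subRate,insRate,delRate Per-residue edit rates in `[0, 1)`.
#' @param ambigRate Per-residue N-injection rate.
#' @param seed Integer seed driving all randomness.
#' @return A [FamilySpec-class].
#' @export
familySpec <- function(nFamilies = 200L, membersPerFamily = 4L,
                       rootLengthRange = c(150L, 300L), subRate = 0.10,
                       insRate = 0.005, delRate = 0.005,
                       ambigRate = 0.002, seed = 1L) {
  new("FamilySpec", nFamilies = as.integer(nFamilies),
      membersPerFamily = as.integer(membersPerFamily),
      rootLengthRange = as.integer(rootLengthRange),
      subRate = subRate, insRate = insRate, delRate = delRate,
      ambigRate = ambigRate, seed = as.integer(seed))
}

setMethod("show", "FamilySpec", function(object) {
  cat(sprintf(
    paste0("FamilySpec: %d families x %d members, roots %d-%d nt,\n",
           "  sub %.3f, ins %.3f, del %.3f, ambig %.3f, seed %d\n"),
    object@nFamilies, object@membersPerFamily,
    object@rootLengthRange[1], object@rootLengthRange[2],
    object@subRate, object@insRate, object@delRate, object@ambigRate,
    object@seed))
})

.mutate_member <- function(root, spec) {
  bases <- c("A", "C", "G", "T")
  r <- strsplit(root, "", fixed = TRUE)[[1]]
  n <- length(r)
  # substitutions: always to a different base
  sub <- runif(n) < spec@subRate
  if (any(sub))
    r[sub] <- vapply(r[sub], function(b) sample(setdiff(bases, b), 1L),
                     character(1))
  # single-residue deletions and insertions (inserted after the position)
  del <- runif(n) < spec@delRate
  ins <- runif(n) < spec@insRate
  out <- ifelse(del, "", r)
  if (any(ins))
    out[ins] <- paste0(out[ins],
                       sample(bases, sum(ins), replace = TRUE))
  s <- paste(out, collapse = "")
  # ambiguity injection
  m <- nchar(s)
  amb <- which(runif(m) < spec@ambigRate)
  for (i in amb) substr(s, i, i) <- "N"
  s
}

#' Generate synthetic sequence families
#'
#' Draws, per family, one uniform random root over A/C/G/T and derives
#' each member independently by per-residue substitution, single-residue
#' insertion/deletion, and N injection at the spec's rates. Identifiers
#' encode family and member (`F0001_M1`, ...); the description carries
#' the family label. Deterministic: equal specs yield identical
#' sequences, and the caller's RNG state is left untouched.
#'
#' @param spec A [FamilySpec-class].
#' @return A DNA [SeqSet-class] of `nFamilies * membersPerFamily`
#'   sequences.
#' @seealso [splitBenchmark()], [familyOf()]
#' @export
generateFamilies <- function(spec) {
  stopifnot(is(spec, "FamilySpec"))
  validObject(spec)
  .with_seed(spec@seed, {
    bases <- c("A", "C", "G", "T")
    ids <- character(0); descs <- character(0); seqs <- character(0)
    for (f in seq_len(spec@nFamilies)) {
      len <- sample(spec@rootLengthRange[1]:spec@rootLengthRange[2], 1L)
      root <- paste(sample(bases, len, replace = TRUE), collapse = "")
      fam <- sprintf("F%04d", f)
      for (m in seq_len(spec@membersPerFamily)) {
        ids <- c(ids, sprintf("%s_M%d", fam, m))
        descs <- c(descs, sprintf("family=%s", fam))
        seqs <- c(seqs, .mutate_member(root, spec))
      }
    }
    SeqSet(seqs, id = ids, desc = descs, alphabet = "dna")
  })
}

#' Family label of benchmark sequence ids
#'
#' @param id Character vector of ids as produced by
#'   [generateFamilies()] (`F0001_M2` -> `F0001`).
#' @return Character vector of family labels.
#' @export
familyOf <- function(id) sub("_M[0-9]+$", "", id)

#' Split families into a query set and a reference database
#'
#' Selects one seeded-random member per family as a query; all remaining
#' members form the database. Every family must have at least 2 members.
#'
#' @param families A [SeqSet-class] from [generateFamilies()].
#' @param seed Integer seed for the per-family member draw.
#' @return List with `queries` and `database` ([SeqSet-class]s, disjoint)
#'   and `truth`, a named character vector mapping each query id to its
#'   family label.
#' @export
splitBenchmark <- function(families, seed = 1L) {
  stopifnot(is(families, "SeqSet"))
  fam <- familyOf(families@id)
  sizes <- table(fam)
  if (any(sizes < 2L))
    stop("every family must have >= 2 members; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  .with_seed(seed, {
    qidx <- vapply(split(seq_along(fam), fam), function(ix)
      ix[sample.int(length(ix), 1L)], integer(1))
    qidx <- sort(unname(qidx))
    queries <- families[qidx]
    database <- families[setdiff(seq_along(fam), qidx)]
    list(queries = queries, database = database,
         truth = stats::setNames(fam[qidx], families@id[qidx]))
  })
}

#' Top-1 family-recovery accuracy of a hit table
#'
#' The fraction of queries whose first accepted hit belongs to the
#' query's own family; queries with no hit count as failures.
#'
#' @param hits Hit data frame from [blastSearch()] / [searchIndex()].
#' @param truth Named character vector (query id -> family label) as
#'   from [splitBenchmark()].
#' @return Fraction in `[0, 1]`.
#' @export
scoreAccuracy <- function(hits, truth) {
  if (length(truth) == 0L) stop("empty truth map")
  top <- hits[!duplicated(hits$query_id), , drop = FALSE]
  hit_fam <- stats::setNames(familyOf(top$target_id), top$query_id)
  # queries with no hit produce NA here; count them as failures
  correct <- hit_fam[names(truth)] == truth
  correct[is.na(correct)] <- FALSE
  mean(correct)
}
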