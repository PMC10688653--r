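test_that("a query identical to one database sequence yields that hit at identity 1", {
  set.seed(73)
  db <- SeqSet(vapply(rep(120, 6), rand_dna, character(1)),
               id = sprintf("t%d", 1:6))
  q <- db[3]
  hits <- blastSearch(q, db)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$target_id, "t3")
  expect_identical(hits$identity, 1)
  expect_identical(hits$strand, "+")
  expect_identical(c(hits$q.start, hits$q.end), c(1L, 120L))
  expect_identical(hits$cigar, "120M")
})

test_that("below-threshold candidates are rejected and the loop stops at the budget", {
  set.seed(79)
  root <- rand_dna(150)
  # 20 candidates at ~20% divergence: plenty of shared k-mers, and every
  # alignment sits near 80% identity — below a 0.9 cutoff
  db <- SeqSet(vapply(1:20, function(i) mutate_subs(root, 30),
                      character(1)), id = sprintf("t%02d", 1:20))
  q <- SeqSet(root, id = "q")
  ix <- buildIndex(db)
  expect_gt(nrow(countShared(q, ix)), 8L)  # more candidates than budget
  res <- searchIndex(q, ix, minIdentity = 0.9, stats = TRUE)
  expect_identical(nrow(res$hits), 0L)
  expect_identical(unname(res$nAligned["q"]), 8L)  # stopped at maxRejects
})

test_that("alignment count never exceeds the accept plus reject budget", {
  set.seed(83)
  fams <- generateFamilies(familySpec(nFamilies = 15, membersPerFamily = 3,
                                      rootLengthRange = c(80L, 140L),
                                      seed = 5))
  split <- splitBenchmark(fams, seed = 5)
  ix <- buildIndex(split$database)
  for (budget in list(c(1L, 8L), c(2L, 3L), c(5L, 1L))) {
    res <- searchIndex(split$queries, ix, maxAccepts = budget[1],
                       maxRejects = budget[2], stats = TRUE)
    expect_true(all(res$nAligned <= sum(budget)))
    # accepted hits per query never exceed maxAccepts
    expect_true(all(table(res$hits$query_id) <= budget[1]))
  }
})

test_that("the first accepted hit comes from the highest-U feasible candidate", {
  set.seed(89)
  root <- rand_dna(150)
  db <- SeqSet(c(mutate_subs(root, 8), mutate_subs(root, 40)),
               id = c("close", "far"))
  q <- SeqSet(root, id = "q")
  ix <- buildIndex(db)
  u <- countShared(q, ix)
  expect_identical(u$target_id[1], "close")
  hits <- searchIndex(q, ix, maxAccepts = 2L)
  expect_identical(hits$target_id[1], "close")
})

test_that("minus-strand hits are found, mapped back, and strand-labelled", {
  set.seed(97)
  db <- SeqSet(vapply(rep(130, 4), rand_dna, character(1)),
               id = sprintf("t%d", 1:4))
  q <- reverseComplement(db[2])
  hits <- blastSearch(q, db, strand = "both")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$target_id, "t2")
  expect_identical(hits$strand, "-")
  expect_identical(hits$identity, 1)
  expect_identical(c(hits$q.start, hits$q.end), c(1L, 130L))
  # plus-only search misses it
  expect_identical(nrow(blastSearch(q, db, strand = "plus")), 0L)
  # minus-only finds it
  expect_identical(blastSearch(q, db, strand = "minus")$target_id, "t2")
})

test_that("both-strand search equals the merged-ranking replay of per-strand candidates", {
  set.seed(101)
  fams <- generateFamilies(familySpec(nFamilies = 12, membersPerFamily = 3,
                                      rootLengthRange = c(100L, 160L),
                                      ambigRate = 0, seed = 11))
  split <- splitBenchmark(fams, seed = 11)
  # reverse-complement half the queries so both strands are exercised
  q <- split$queries
  flip <- seq(1, length(q), by = 2)
  for (i in flip) q@seq[i] <- kblast:::.revcomp_chr(q@seq[i])
  ix <- buildIndex(split$database)
  hits <- searchIndex(q, ix, strand = "both")
  # oracle: per query, merge the two candidate lists by (U desc, target
  # asc, plus first) and replay the accept/reject loop with alignPair
  for (i in seq_along(q)) {
    plus <- countShared(q[i], ix)
    minus <- countShared(kblast:::.revcomp_chr(q@seq[i]), ix)
    plus$strand <- rep("+", nrow(plus))
    minus$strand <- rep("-", nrow(minus))
    cand <- rbind(plus, minus)
    cand <- cand[order(-cand$u, cand$target,
                       match(cand$strand, c("+", "-"))), ]
    accepts <- 0; rejects <- 0; expect_hit <- NULL
    for (r in seq_len(nrow(cand))) {
      if (accepts >= 1 || rejects >= 8) break
      oq <- if (cand$strand[r] == "+") q@seq[i] else
        kblast:::.revcomp_chr(q@seq[i])
      a <- alignPair(oq, as.character(split$database)[[cand$target_id[r]]],
                     "dna")
      if (!is.null(a) && a$identity >= 0.75) {
        accepts <- accepts + 1
        expect_hit <- c(cand$target_id[r], cand$strand[r])
      } else rejects <- rejects + 1
    }
    got <- hits[hits$query_id == q@id[i], ]
    if (is.null(expect_hit)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(c(got$target_id[1], got$strand[1]), expect_hit)
    }
  }
})

test_that("protein searches run plus-only and reject strand flags", {
  set.seed(103)
  db <- SeqSet(vapply(rep(60, 4), rand_protein, character(1)),
               id = sprintf("p%d", 1:4), alphabet = "protein")
  hits <- blastSearch(db, db)
  expect_identical(hits$target_id, db@id)
  expect_true(all(hits$strand == "n/a"))
  expect_error(blastSearch(db[1], db, strand = "both"), "protein")
  expect_error(blastSearch(db[1], db, strand = "minus"), "protein")
})

test_that("searching a database against itself recovers every sequence", {
  set.seed(107)
  db <- SeqSet(vapply(sample(60:200, 40, replace = TRUE), rand_dna,
                      character(1)), id = sprintf("s%02d", 1:40))
  hits <- blastSearch(db, db)
  expect_identical(nrow(hits), 40L)
  expect_identical(hits$query_id, db@id)
  expect_true(all(hits$identity == 1))
  seqs <- as.character(db)
  expect_true(all(seqs[hits$query_id] == seqs[hits$target_id]))
})

test_that("zero queries give an empty, well-formed hit table", {
  db <- SeqSet(rand_dna(60))
  hits <- searchIndex(db[integer(0)], buildIndex(db))
  expect_identical(nrow(hits), 0L)
  expect_identical(names(hits), kblast:::.HIT_COLUMNS)
})

test_that("queries too short for any k-mer return empty with a warning", {
  db <- SeqSet(rand_dna(60), id = "t")
  q <- SeqSet("ACGT", id = "tiny")
  expect_warning(hits <- searchIndex(q, buildIndex(db, k = 8)),
                 "shorter than k")
  expect_identical(nrow(hits), 0L)
})

test_that("repeated runs produce byte-identical hit tables", {
  set.seed(109)
  fams <- generateFamilies(familySpec(nFamilies = 10, membersPerFamily = 3,
                                      rootLengthRange = c(90L, 150L),
                                      seed = 3))
  split <- splitBenchmark(fams, seed = 3)
  f1 <- tempfile(); f2 <- tempfile()
  blastSearch(split$queries, split$database, output = f1)
  blastSearch(split$queries, split$database, output = f2)
  expect_identical(readLines(f1), readLines(f2))
})
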