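test_that("seed finding reports merged maximal exact matches", {
  set.seed(31)
  s <- rand_dna(60)
  # identical repeat-free sequences: one maximal full-diagonal seed
  seeds <- findSeeds(s, s, k = 8, alphabet = "dna")
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$qpos, 0L)
  expect_identical(seeds$length, 60L)
  # fully disjoint sequences: none
  expect_identical(nrow(findSeeds(strrep("A", 40), strrep("C", 40),
                                  k = 8, alphabet = "dna")), 0L)
})

test_that("an implanted shared 12-mer is seeded exactly where the brute-force scan puts it", {
  set.seed(37)
  repeat {  # draw until the 12-mer occurs nowhere else in either sequence
    q <- rand_dna(80)
    t <- rand_dna(80)
    core <- rand_dna(12)
    substr(q, 31, 42) <- core
    substr(t, 51, 62) <- core
    k <- 8
    hitgrid <- outer(1:(80 - k + 1), 1:(80 - k + 1), Vectorize(function(i, j)
      substr(q, i, i + k - 1) == substr(t, j, j + k - 1)))
    if (sum(hitgrid) == 12 - k + 1) break
  }
  seeds <- findSeeds(q, t, k = 8, alphabet = "dna")
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$qpos, 30L)
  expect_identical(seeds$tpos, 50L)
  expect_identical(seeds$length, 12L)
})

test_that("X-drop extension spans identical sequences and stops at mismatch walls", {
  s <- rand_dna(50)
  h <- extendSeed(s, s, qpos = 20, tpos = 20, length = 8,
                  alphabet = "dna")
  expect_identical(c(h$qs, h$qe), c(0L, 50L))
  expect_identical(h$score, 100L)  # 50 * match(+2)
  # seed flanked by walls deeper than xdrop: the HSP is the seed itself
  wall <- strrep("C", 20)
  q <- paste0(wall, "ACGTACGT", wall)
  t <- paste0(strrep("G", 20), "ACGTACGT", strrep("T", 20))
  h <- extendSeed(q, t, qpos = 20, tpos = 20, length = 8,
                  alphabet = "dna", xdrop = 16)
  expect_identical(c(h$qs, h$qe, h$ts, h$te), c(20L, 28L, 20L, 28L))
  expect_identical(h$score, 16L)
})

test_that("extension endpoints match the exhaustive ungapped-extension oracle", {
  set.seed(41)
  dna <- dnaAlphabet()
  sm <- scoreMatrix(dna)
  for (i in 1:30) {
    q <- rand_dna(100)
    t <- mutate_subs(q, sample(5:25, 1))
    seeds <- findSeeds(q, t, k = 8, alphabet = "dna")
    if (nrow(seeds) == 0) next
    sd <- seeds[1, ]
    h <- extendSeed(q, t, sd$qpos, sd$tpos, sd$length,
                    alphabet = "dna", xdrop = 20)
    # oracle: best-scoring ungapped endpoints over all extensions
    qv <- strsplit(q, "")[[1]]
    tv <- strsplit(t, "")[[1]]
    col <- function(qi, ti) sm[qv[qi], tv[ti]]
    # right: cumulative over positions past the seed
    rmax <- min(100 - (sd$qpos + sd$length), 100 - (sd$tpos + sd$length))
    rcum <- if (rmax > 0) cumsum(vapply(seq_len(rmax), function(x)
      col(sd$qpos + sd$length + x, sd$tpos + sd$length + x),
      numeric(1))) else numeric(0)
    rbest <- max(0, rcum)
    rext <- if (rbest > 0) which.max(rcum) else 0L
    lmax <- min(sd$qpos, sd$tpos)
    lcum <- if (lmax > 0) cumsum(vapply(seq_len(lmax), function(x)
      col(sd$qpos + 1 - x, sd$tpos + 1 - x), numeric(1))) else numeric(0)
    lbest <- max(0, lcum)
    lext <- if (lbest > 0) which.max(lcum) else 0L
    seed_score <- sum(vapply(seq_len(sd$length), function(x)
      col(sd$qpos + x, sd$tpos + x), numeric(1)))
    expect_identical(h$qs, sd$qpos - lext)
    expect_identical(h$qe, sd$qpos + sd$length + rext)
    expect_identical(h$score, as.integer(seed_score + lbest + rbest))
  }
})

test_that("greedy chaining follows the stated rule", {
  one <- data.frame(qs = 0L, qe = 10L, ts = 0L, te = 10L, score = 20L)
  expect_identical(chainHsps(one), one)
  # two HSPs overlapping in target only: the higher-scoring one alone
  two <- data.frame(qs = c(0L, 40L), qe = c(10L, 50L),
                    ts = c(5L, 9L), te = c(15L, 19L),
                    score = c(20L, 35L))
  expect_identical(chainHsps(two), two[2, ])
  expect_identical(nrow(chainHsps(two[0, ])), 0L)
  # random sets against the literal greedy oracle
  set.seed(43)
  for (i in 1:50) {
    hsps <- random_hsps(sample(2:9, 1))
    got <- chainHsps(hsps)
    want <- greedy_chain_oracle(hsps)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("banded DP reproduces forced paths and the full-matrix oracle", {
  expect_identical(bandedAlign("", "ACG", "dna"),
                   list(cigar = "3D", score = -11L))
  expect_identical(bandedAlign("ACGT", "ACGT", "dna"),
                   list(cigar = "4M", score = 8L))
  dna <- dnaAlphabet()
  set.seed(47)
  for (i in 1:40) {
    a <- rand_dna(sample(1:30, 1))
    b <- rand_dna(sample(1:30, 1))
    got <- bandedAlign(a, b, "dna", bandRadius = 30)
    want <- nw_affine_score(a, b, scoreMatrix(dna), 5, 2)
    expect_identical(got$score, as.integer(want))
    # the reported cigar re-scores to the reported score
    chk <- score_cigar_oracle(got$cigar, a, b, 0, 0,
                              scoreMatrix(dna), 5, 2)
    expect_identical(as.integer(chk$score), got$score)
  }
})

test_that("a full-coverage band equals unrestricted global alignment", {
  set.seed(53)
  aa <- proteinAlphabet()
  for (i in 1:10) {
    a <- rand_protein(25)
    b <- rand_protein(sample(15:35, 1))
    full <- bandedAlign(a, b, aa, bandRadius = max(nchar(a), nchar(b)))
    expect_identical(full$score,
                     as.integer(nw_affine_score(a, b, scoreMatrix(aa),
                                                11, 1)))
  }
  # band auto-widens so a path exists even at radius 1
  r <- bandedAlign("ACGT", "ACGTACGTACGT", "dna", bandRadius = 1)
  expect_match(r$cigar, "D")
})

test_that("alignPair recovers identity on mutated copies", {
  q <- strrep("ACGTTGAC", 12)
  expect_identical(alignPair(q, q, "dna")$identity, 1)
  expect_match(alignPair(q, q, "dna")$cigar, "^96M$")
  set.seed(59)
  repeat {  # single mid-sequence substitution in a repeat-free 100-mer
    q <- rand_dna(100)
    if (nrow(findSeeds(q, q, 8, "dna")) == 1) break
  }
  t <- q
  substr(t, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, 50, 50))[1]
  a <- alignPair(q, t, "dna")
  expect_identical(a$length, 100L)
  expect_identical(a$identity, 0.99)
  expect_null(alignPair(strrep("A", 50), strrep("C", 50), "dna"))
})

test_that("extended CIGAR spells out matches and mismatches", {
  q <- strrep("ACGTTGCA", 8)
  t <- q
  substr(t, 30, 30) <- "A"  # was G
  a <- alignPair(q, t, "dna", extendedCigar = TRUE)
  expect_identical(a$cigar, "29=1X34=")
})

test_that("reported scores re-evaluate exactly from their CIGARs", {
  set.seed(61)
  dna <- dnaAlphabet()
  for (i in 1:25) {
    q <- rand_dna(150)
    t <- mutate_subs(q, sample(3:25, 1))
    # occasionally delete a block to force a bridge
    if (i %% 3 == 0) t <- paste0(substr(t, 1, 60), substr(t, 66, 150))
    a <- alignPair(q, t, "dna")
    expect_false(is.null(a))
    chk <- score_cigar_oracle(a$cigar, q, t, a$qs, a$ts,
                              scoreMatrix(dna), 5, 2)
    expect_identical(as.integer(chk$score), a$score)
    expect_identical(as.integer(chk$matches), a$matches)
    expect_identical(as.integer(chk$columns), a$length)
    expect_identical(a$identity, a$matches / a$length)
  }
})

test_that("identity is symmetric and degrades monotonically in mutations", {
  set.seed(67)
  q <- rand_dna(180)
  muts <- sample(180)  # one fixed mutation order, positions distinct
  prev <- 1
  t <- q
  bases <- c("A", "C", "G", "T")
  for (nm in c(4, 12, 24, 40)) {
    t <- q
    for (p in muts[seq_len(nm)])
      substr(t, p, p) <- setdiff(bases, substr(q, p, p))[1]
    a <- alignPair(q, t, "dna")
    ident <- if (is.null(a)) 0 else a$identity
    expect_lte(ident, prev)
    prev <- ident
    # symmetry under role swap
    b <- alignPair(t, q, "dna")
    if (!is.null(a)) expect_identical(b$identity, a$identity)
  }
})

test_that("identityOf recounts matching columns over all columns", {
  a <- list(matches = 95L, length = 100L)
  expect_identical(identityOf(a), 0.95)
  expect_true(is.na(identityOf(NULL)))
  set.seed(71)
  q <- rand_dna(120)
  t <- mutate_subs(q, 10)
  al <- alignPair(q, t, "dna")
  expect_identical(identityOf(al), al$identity)
})
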