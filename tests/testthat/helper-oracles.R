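# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive re-implementations (string sets, full
# dynamic programming, literal greedy loops) kept independent of the
# package's engine.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# copy of x with nsub random substitutions at distinct positions
mutate_subs <- function(x, nsub) {
  bases <- c("A", "C", "G", "T")
  r <- strsplit(x, "")[[1]]
  pos <- sample(length(r), nsub)
  for (p in pos) r[p] <- sample(setdiff(bases, r[p]), 1)
  paste(r, collapse = "")
}

# Brute-force unique-k-mer set of a sequence as literal window strings,
# excluding any window containing an ambiguity code.
kmer_set_oracle <- function(seq, k, canonical = c("A", "C", "G", "T")) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  ok <- !grepl(sprintf("[^%s]", paste(canonical, collapse = "")), w)
  unique(w[ok])
}

# Full-matrix Needleman-Wunsch-Gotoh global affine alignment, score only.
# Pure R; used on tiny cases to triangulate the scoring convention.
nw_affine_score <- function(a, b, smat, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  GX <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  GY <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (n > 0) GX[2:(n + 1), 1] <- -(open + (1:n) * ext)
  if (m > 0) GY[1, 2:(m + 1)] <- -(open + (1:m) * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- smat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], GX[i, j], GY[i, j]) + s
      GX[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              GX[i, j + 1] - ext,
                              GY[i, j + 1] - open - ext)
      GY[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              GX[i + 1, j] - open - ext,
                              GY[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], GX[n + 1, m + 1], GY[n + 1, m + 1])
}

# Independent full-DP global affine score via Biostrings (fast volume
# oracle; same gap convention: a length-L run costs open + L * ext).
bio_global_score <- function(a, b, smat, open, ext) {
  Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = smat, gapOpening = open,
    gapExtension = ext, type = "global", scoreOnly = TRUE)
}

# Literal transcription of the greedy chaining rule: take the
# highest-scoring HSP, then repeatedly add the highest-scoring remaining
# HSP collinear with and non-overlapping (both coordinates) with every
# selected HSP. Ties: higher score, then smaller qs, then smaller ts.
greedy_chain_oracle <- function(hsps) {
  compat <- function(a, b) {
    (a$qe <= b$qs && a$te <= b$ts) || (b$qe <= a$qs && b$te <= a$ts)
  }
  rows <- split(hsps, seq_len(nrow(hsps)))
  ord <- order(-hsps$score, hsps$qs, hsps$ts)
  selected <- integer(0)
  repeat {
    pick <- NA_integer_
    for (i in ord) {
      if (i %in% selected) next
      if (all(vapply(selected, function(s)
        compat(rows[[i]], rows[[s]]), logical(1)))) {
        pick <- i
        break
      }
    }
    if (is.na(pick)) break
    selected <- c(selected, pick)
  }
  sort_by_q <- selected[order(hsps$qs[selected])]
  hsps[sort_by_q, , drop = FALSE]
}

# Re-evaluate a CIGAR against the two sequences under the scorer:
# returns list(score, matches, columns). qs/ts are 0-based starts.
score_cigar_oracle <- function(cigar, q, t, qs, ts, smat, open, ext) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDX=]", cigar))[[1]]
  qi <- qs
  ti <- ts
  score <- 0
  matches <- 0
  columns <- 0
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  for (o in ops) {
    len <- as.integer(sub("[MIDX=]", "", o))
    op <- sub("[0-9]+", "", o)
    columns <- columns + len
    if (op %in% c("M", "=", "X")) {
      for (x in seq_len(len)) {
        score <- score + smat[qv[qi + x], tv[ti + x]]
        if (qv[qi + x] == tv[ti + x]) matches <- matches + 1
      }
      qi <- qi + len
      ti <- ti + len
    } else if (op == "I") {
      score <- score - open - len * ext
      qi <- qi + len
    } else {
      score <- score - open - len * ext
      ti <- ti + len
    }
  }
  list(score = score, matches = matches, columns = columns)
}

# random synthetic HSP set for chaining tests
random_hsps <- function(n, span = 200L) {
  qs <- sample.int(span, n, replace = TRUE)
  ts <- sample.int(span, n, replace = TRUE)
  len <- sample(8:40, n, replace = TRUE)
  data.frame(qs = qs, qe = qs + len, ts = ts, te = ts + len,
             score = sample(5:120, n, replace = TRUE))
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
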