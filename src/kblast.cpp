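// Core engine: k-mer encoding and indexing, U counting, seed-and-extend
// HSP discovery, greedy chaining, banded affine-gap DP, and the
// accept/reject search driver.
//
// Conventions shared with the R layer:
//  - residues are uppercase, pre-validated by the R constructors;
//  - k-mer codes are big-endian packed unsigned 32-bit values; any window
//    touching an ambiguous residue is dropped (the AmbiguousKmer sentinel
//    is never stored);
//  - all positions at this level are 0-based; half-open intervals;
//  - CIGAR ops: M (column), I (query-only), D (target-only); '='/'X' in
//    extended mode;
//  - gap penalties are positive numbers subtracted from the score; a gap
//    run of length L costs open + L * extend.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int CODE_AMBIG = -1;
static const int CODE_INVALID = -2;
static const int NEG_INF = std::numeric_limits<int>::min() / 4;

struct AlphaEnc {
  int bits;
  int code[256];
};

static AlphaEnc make_enc(const std::string& name) {
  AlphaEnc e;
  e.bits = 0;
  for (int i = 0; i < 256; ++i) e.code[i] = CODE_INVALID;
  if (name == "dna") {
    e.bits = 2;
    e.code[(unsigned char)'A'] = 0;
    e.code[(unsigned char)'C'] = 1;
    e.code[(unsigned char)'G'] = 2;
    e.code[(unsigned char)'T'] = 3;
    const char* amb = "RYSWKMBDHVN";
    for (const char* p = amb; *p; ++p) e.code[(unsigned char)*p] = CODE_AMBIG;
  } else if (name == "protein") {
    e.bits = 5;
    const char* aa = "ACDEFGHIKLMNPQRSTVWY";  // 0..19, alphabetical
    for (int i = 0; aa[i]; ++i) e.code[(unsigned char)aa[i]] = i;
    const char* amb = "BZJXUO";
    for (const char* p = amb; *p; ++p) e.code[(unsigned char)*p] = CODE_AMBIG;
  } else {
    stop("unknown alphabet: '%s'", name.c_str());
  }
  return e;
}

// Enumerate valid (ambiguity-free) k-mer windows of s.
static void kmer_codes(const std::string& s, int k, const AlphaEnc& e,
                       std::vector<int>& pos, std::vector<uint32_t>& codes) {
  int n = (int)s.size();
  if (k < 1 || n < k) return;
  uint64_t mask = (uint64_t(e.bits) * k >= 64)
                      ? ~uint64_t(0)
                      : ((uint64_t(1) << (uint64_t)(e.bits * k)) - 1);
  uint64_t cur = 0;
  int lastBad = -1;
  for (int i = 0; i < n; ++i) {
    int c = e.code[(unsigned char)s[i]];
    if (c < 0) {
      lastBad = i;
      c = 0;
    }
    cur = ((cur << e.bits) | (uint64_t)c) & mask;
    int start = i - k + 1;
    if (start >= 0 && lastBad < start) {
      pos.push_back(start);
      codes.push_back((uint32_t)cur);
    }
  }
}

static void unique_codes(const std::string& s, int k, const AlphaEnc& e,
                         std::vector<uint32_t>& out) {
  std::vector<int> pos;
  kmer_codes(s, k, e, pos, out);
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// [[Rcpp::export(name = ".cpp_enumerate_kmers")]]
List cpp_enumerate_kmers(std::string seq, int k, std::string alphabet) {
  AlphaEnc e = make_enc(alphabet);
  if ((uint64_t)e.bits * k > 32) stop("k * bits_per_symbol exceeds 32");
  std::vector<int> pos;
  std::vector<uint32_t> codes;
  kmer_codes(seq, k, e, pos, codes);
  NumericVector cd(codes.size());
  IntegerVector ps(pos.size());
  for (size_t i = 0; i < codes.size(); ++i) {
    cd[i] = (double)codes[i];
    ps[i] = pos[i];
  }
  return List::create(_["pos"] = ps, _["code"] = cd);
}

// ---------------------------------------------------------------------------
// Database index: per-k-mer postings of database sequence ids (presence only)
// ---------------------------------------------------------------------------

struct KIndex {
  int k;
  std::string alphabet;
  AlphaEnc enc;
  std::vector<std::string> seqs;
  std::unordered_map<uint32_t, std::vector<int>> postings;
};

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, int k, std::string alphabet) {
  XPtr<KIndex> xp(new KIndex(), true);
  xp->k = k;
  xp->alphabet = alphabet;
  xp->enc = make_enc(alphabet);
  if (k < 1) stop("k must be >= 1");
  if ((uint64_t)xp->enc.bits * k > 32) stop("k * bits_per_symbol exceeds 32");
  int n = seqs.size();
  xp->seqs.reserve(n);
  std::vector<uint32_t> uq;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    uq.clear();
    unique_codes(s, k, xp->enc, uq);
    for (uint32_t c : uq) xp->postings[c].push_back(i);
    xp->seqs.push_back(std::move(s));
  }
  return xp;
}

// [[Rcpp::export(name = ".cpp_index_info")]]
List cpp_index_info(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  return List::create(_["k"] = xp->k, _["alphabet"] = xp->alphabet,
                      _["n_sequences"] = (int)xp->seqs.size(),
                      _["n_kmers"] = (double)xp->postings.size());
}

// Dump all postings (small indexes / tests only). Ids returned 0-based.
// [[Rcpp::export(name = ".cpp_index_dump")]]
List cpp_index_dump(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  std::vector<uint32_t> keys;
  keys.reserve(xp->postings.size());
  for (auto& kv : xp->postings) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector code(keys.size());
  List ids(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    code[i] = (double)keys[i];
    const std::vector<int>& v = xp->postings[keys[i]];
    ids[i] = IntegerVector(v.begin(), v.end());
  }
  return List::create(_["code"] = code, _["ids"] = ids);
}

struct Cand {
  int target;
  int u;
  int strand;  // 0 plus, 1 minus
};

static void count_shared_core(const KIndex& ix, const std::string& query,
                              int strand, std::vector<Cand>& out) {
  std::vector<uint32_t> uq;
  unique_codes(query, ix.k, ix.enc, uq);
  std::vector<int> counts(ix.seqs.size(), 0);
  for (uint32_t c : uq) {
    auto it = ix.postings.find(c);
    if (it == ix.postings.end()) continue;
    for (int t : it->second) ++counts[t];
  }
  for (size_t t = 0; t < counts.size(); ++t)
    if (counts[t] > 0) out.push_back(Cand{(int)t, counts[t], strand});
}

static bool cand_less(const Cand& a, const Cand& b) {
  if (a.u != b.u) return a.u > b.u;          // decreasing U
  if (a.target != b.target) return a.target < b.target;
  return a.strand < b.strand;                // plus before minus
}

// [[Rcpp::export(name = ".cpp_count_shared")]]
List cpp_count_shared(SEXP xp_, std::string query) {
  XPtr<KIndex> xp(xp_);
  std::vector<Cand> cands;
  count_shared_core(*xp, query, 0, cands);
  std::stable_sort(cands.begin(), cands.end(), cand_less);
  IntegerVector target(cands.size()), u(cands.size());
  for (size_t i = 0; i < cands.size(); ++i) {
    target[i] = cands[i].target;  // 0-based; R layer shifts
    u[i] = cands[i].u;
  }
  return List::create(_["target"] = target, _["u"] = u);
}

// ---------------------------------------------------------------------------
// Scoring
// ---------------------------------------------------------------------------

struct Scorer {
  std::vector<int> tab;  // 256 x 256
  int open, ext;
  int at(unsigned char a, unsigned char b) const { return tab[(size_t)a * 256 + b]; }
};

static Scorer make_scorer(IntegerMatrix m, CharacterVector letters, int open,
                          int ext) {
  Scorer sc;
  sc.tab.assign(256 * 256, NEG_INF);
  sc.open = open;
  sc.ext = ext;
  int n = letters.size();
  if (m.nrow() != n || m.ncol() != n) stop("score matrix / letters mismatch");
  std::vector<unsigned char> ch(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(letters[i]);
    if (s.size() != 1) stop("score letters must be single characters");
    ch[i] = (unsigned char)s[0];
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) sc.tab[(size_t)ch[i] * 256 + ch[j]] = m(i, j);
  return sc;
}

// ---------------------------------------------------------------------------
// Seeds
// ---------------------------------------------------------------------------

struct Seed {
  int qpos, tpos, len;
};

// All maximal exact-match runs of ambiguity-free k-mer windows, ordered by
// diagonal (tpos - qpos) then query position.
static void find_seeds_core(const std::string& q, const std::string& t, int k,
                            const AlphaEnc& e, std::vector<Seed>& seeds) {
  std::vector<int> qpos, tpos;
  std::vector<uint32_t> qcode, tcode;
  kmer_codes(q, k, e, qpos, qcode);
  kmer_codes(t, k, e, tpos, tcode);
  if (qcode.empty() || tcode.empty()) return;
  std::unordered_map<uint32_t, std::vector<int>> tmap;
  for (size_t i = 0; i < tcode.size(); ++i) tmap[tcode[i]].push_back(tpos[i]);
  // raw matches keyed by diagonal
  std::vector<std::pair<int64_t, int>> raw;  // (diag, qpos)
  for (size_t i = 0; i < qcode.size(); ++i) {
    auto it = tmap.find(qcode[i]);
    if (it == tmap.end()) continue;
    for (int tp : it->second)
      raw.push_back({(int64_t)tp - qpos[i], qpos[i]});
  }
  std::sort(raw.begin(), raw.end());
  size_t i = 0;
  while (i < raw.size()) {
    int64_t d = raw[i].first;
    int qs = raw[i].second;
    int qe = qs + k;
    size_t j = i + 1;
    // merge overlapping or adjacent windows on the same diagonal: both are
    // exact matches, so their union is residue-identical
    while (j < raw.size() && raw[j].first == d && raw[j].second <= qe) {
      qe = std::max(qe, raw[j].second + k);
      ++j;
    }
    seeds.push_back(Seed{qs, (int)(qs + d), qe - qs});
    i = j;
  }
}

// [[Rcpp::export(name = ".cpp_find_seeds")]]
DataFrame cpp_find_seeds(std::string q, std::string t, int k,
                         std::string alphabet) {
  AlphaEnc e = make_enc(alphabet);
  std::vector<Seed> seeds;
  find_seeds_core(q, t, k, e, seeds);
  IntegerVector qp(seeds.size()), tp(seeds.size()), ln(seeds.size());
  for (size_t i = 0; i < seeds.size(); ++i) {
    qp[i] = seeds[i].qpos;
    tp[i] = seeds[i].tpos;
    ln[i] = seeds[i].len;
  }
  return DataFrame::create(_["qpos"] = qp, _["tpos"] = tp, _["length"] = ln);
}

// ---------------------------------------------------------------------------
// Ungapped X-drop extension
// ---------------------------------------------------------------------------

struct Hsp {
  int qs, qe, ts, te;  // half-open; qe - qs == te - ts (ungapped)
  int score;
};

static Hsp extend_seed_core(const std::string& q, const std::string& t,
                            const Seed& sd, const Scorer& sc, int xdrop) {
  int seedScore = 0;
  for (int i = 0; i < sd.len; ++i)
    seedScore += sc.at(q[sd.qpos + i], t[sd.tpos + i]);
  // right
  int run = 0, best = 0;
  int bq = sd.qpos + sd.len, bt = sd.tpos + sd.len;
  int i = bq, j = bt;
  int nq = (int)q.size(), nt = (int)t.size();
  while (i < nq && j < nt) {
    run += sc.at(q[i], t[j]);
    ++i;
    ++j;
    if (run > best) {
      best = run;
      bq = i;
      bt = j;
    }
    if (best - run > xdrop) break;
  }
  int rightGain = best;
  int qe = bq, te = bt;
  // left
  run = 0;
  best = 0;
  int lq = sd.qpos, lt = sd.tpos;
  i = lq - 1;
  j = lt - 1;
  while (i >= 0 && j >= 0) {
    run += sc.at(q[i], t[j]);
    if (run > best) {
      best = run;
      lq = i;
      lt = j;
    }
    if (best - run > xdrop) break;
    --i;
    --j;
  }
  int leftGain = best;
  return Hsp{lq, qe, lt, te, seedScore + leftGain + rightGain};
}

// [[Rcpp::export(name = ".cpp_extend_seed")]]
List cpp_extend_seed(std::string q, std::string t, int qpos, int tpos, int len,
                     IntegerMatrix scoreMat, CharacterVector letters, int open,
                     int ext, int xdrop) {
  Scorer sc = make_scorer(scoreMat, letters, open, ext);
  Hsp h = extend_seed_core(q, t, Seed{qpos, tpos, len}, sc, xdrop);
  return List::create(_["qs"] = h.qs, _["qe"] = h.qe, _["ts"] = h.ts,
                      _["te"] = h.te, _["score"] = h.score);
}

// ---------------------------------------------------------------------------
// Greedy chaining
// ---------------------------------------------------------------------------

// Compatible = strictly collinear, non-overlapping in BOTH coordinates
// (adjacency allowed: intervals are half-open).
static bool hsp_compatible(const Hsp& a, const Hsp& b) {
  return (a.qe <= b.qs && a.te <= b.ts) || (b.qe <= a.qs && b.te <= a.ts);
}

// Greedy rule: pick the highest-scoring HSP; repeatedly add the
// highest-scoring remaining HSP compatible with every selected one.
// Ties: higher score first, then smaller query start, then smaller target
// start. Returns indices into `hsps`, sorted by query coordinate.
static std::vector<int> chain_core(const std::vector<Hsp>& hsps) {
  int n = (int)hsps.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (hsps[a].score != hsps[b].score) return hsps[a].score > hsps[b].score;
    if (hsps[a].qs != hsps[b].qs) return hsps[a].qs < hsps[b].qs;
    return hsps[a].ts < hsps[b].ts;
  });
  std::vector<int> sel;
  std::vector<bool> used(n, false);
  for (;;) {
    int pick = -1;
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      if (used[i]) continue;
      bool ok = true;
      for (int s : sel)
        if (!hsp_compatible(hsps[i], hsps[s])) {
          ok = false;
          break;
        }
      if (ok) {
        pick = i;
        break;
      }
    }
    if (pick < 0) break;
    used[pick] = true;
    sel.push_back(pick);
    // mark incompatible leftovers so the scan shrinks
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      if (!used[i] && !hsp_compatible(hsps[i], hsps[pick])) used[i] = true;
    }
  }
  std::sort(sel.begin(), sel.end(),
            [&](int a, int b) { return hsps[a].qs < hsps[b].qs; });
  return sel;
}

// [[Rcpp::export(name = ".cpp_chain_hsps")]]
IntegerVector cpp_chain_hsps(IntegerVector qs, IntegerVector qe,
                             IntegerVector ts, IntegerVector te,
                             IntegerVector score) {
  int n = qs.size();
  std::vector<Hsp> hsps(n);
  for (int i = 0; i < n; ++i)
    hsps[i] = Hsp{qs[i], qe[i], ts[i], te[i], score[i]};
  std::vector<int> sel = chain_core(hsps);
  IntegerVector out(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) out[i] = sel[i] + 1;  // 1-based
  return out;
}

// ---------------------------------------------------------------------------
// Banded global affine-gap DP (Needleman-Wunsch-Gotoh within a band)
// ---------------------------------------------------------------------------

struct CigarOp {
  char op;
  int len;
};

static void cig_push(std::vector<CigarOp>& c, char op, int len = 1) {
  if (len <= 0) return;
  if (!c.empty() && c.back().op == op)
    c.back().len += len;
  else
    c.push_back(CigarOp{op, len});
}

static std::string cig_text(const std::vector<CigarOp>& c) {
  std::string s;
  for (const CigarOp& o : c) {
    s += std::to_string(o.len);
    s += o.op;
  }
  return s;
}

// Global alignment of a vs b restricted to the band lo <= j - i <= hi around
// the length-shifted main diagonal. Returns score; appends ops to `out`.
// M/'X'/'=' columns are emitted as 'M' here; match flags are recovered by the
// caller from the residues.
static int banded_core(const std::string& a, const std::string& b,
                       const Scorer& sc, int band, std::vector<CigarOp>& out) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0) return 0;
  if (n == 0) {
    cig_push(out, 'D', m);
    return -(sc.open + m * sc.ext);
  }
  if (m == 0) {
    cig_push(out, 'I', n);
    return -(sc.open + n * sc.ext);
  }
  int r = std::max(band, std::abs(m - n));
  int lo = std::min(0, m - n) - r;
  int hi = std::max(0, m - n) + r;
  size_t W = (size_t)(m + 1);
  auto idx = [W](int i, int j) { return (size_t)i * W + j; };
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF), GX = M, GY = M;
  M[idx(0, 0)] = 0;
  for (int j = 1; j <= m && j <= hi; ++j)
    GY[idx(0, j)] = -(sc.open + j * sc.ext);
  for (int i = 1; i <= n && -i >= lo; ++i)
    GX[idx(i, 0)] = -(sc.open + i * sc.ext);
  for (int i = 1; i <= n; ++i) {
    int jlow = std::max(1, i + lo), jhigh = std::min(m, i + hi);
    for (int j = jlow; j <= jhigh; ++j) {
      int s = sc.at(a[i - 1], b[j - 1]);
      int dM = M[idx(i - 1, j - 1)], dX = GX[idx(i - 1, j - 1)],
          dY = GY[idx(i - 1, j - 1)];
      int dbest = std::max(dM, std::max(dX, dY));
      M[idx(i, j)] = (dbest <= NEG_INF) ? NEG_INF : dbest + s;
      // gap in target (consume a_i)
      int uM = M[idx(i - 1, j)], uX = GX[idx(i - 1, j)], uY = GY[idx(i - 1, j)];
      int xo = std::max(uM, uY);
      int xbest = std::max(xo <= NEG_INF ? NEG_INF : xo - sc.open - sc.ext,
                           uX <= NEG_INF ? NEG_INF : uX - sc.ext);
      GX[idx(i, j)] = xbest;
      // gap in query (consume b_j)
      int lM = M[idx(i, j - 1)], lX = GX[idx(i, j - 1)], lY = GY[idx(i, j - 1)];
      int yo = std::max(lM, lX);
      int ybest = std::max(yo <= NEG_INF ? NEG_INF : yo - sc.open - sc.ext,
                           lY <= NEG_INF ? NEG_INF : lY - sc.ext);
      GY[idx(i, j)] = ybest;
    }
  }
  int fM = M[idx(n, m)], fX = GX[idx(n, m)], fY = GY[idx(n, m)];
  int scorev = std::max(fM, std::max(fX, fY));
  // traceback (preference M > I > D on exact ties, fixed for determinism)
  std::vector<CigarOp> rev;
  int i = n, j = m;
  char state = (scorev == fM) ? 'M' : (scorev == fX ? 'I' : 'D');
  while (i > 0 || j > 0) {
    if (state == 'M') {
      int s = sc.at(a[i - 1], b[j - 1]);
      cig_push(rev, 'M');
      int prev = M[idx(i, j)] - s;
      --i;
      --j;
      if (i == 0 && j == 0) break;
      if (M[idx(i, j)] == prev)
        state = 'M';
      else if (GX[idx(i, j)] == prev)
        state = 'I';
      else
        state = 'D';
    } else if (state == 'I') {
      cig_push(rev, 'I');
      int cur = GX[idx(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (GX[idx(i, j)] == cur + sc.ext)
        state = 'I';
      else if (M[idx(i, j)] == cur + sc.open + sc.ext)
        state = 'M';
      else
        state = 'D';
    } else {
      cig_push(rev, 'D');
      int cur = GY[idx(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (GY[idx(i, j)] == cur + sc.ext)
        state = 'D';
      else if (M[idx(i, j)] == cur + sc.open + sc.ext)
        state = 'M';
      else
        state = 'I';
    }
  }
  for (auto it = rev.rbegin(); it != rev.rend(); ++it)
    cig_push(out, it->op, it->len);
  return scorev;
}

// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string a, std::string b, IntegerMatrix scoreMat,
                      CharacterVector letters, int open, int ext, int band) {
  Scorer sc = make_scorer(scoreMat, letters, open, ext);
  std::vector<CigarOp> ops;
  int s = banded_core(a, b, sc, band, ops);
  return List::create(_["cigar"] = cig_text(ops), _["score"] = s);
}

// ---------------------------------------------------------------------------
// Full pairwise alignment: seeds -> HSPs -> chain -> bridge gaps
// ---------------------------------------------------------------------------

struct PairAln {
  bool found;
  int qs, qe, ts, te;  // half-open, on the oriented query / target
  int score;
  int matches, length;  // matching columns / total columns
  std::vector<CigarOp> cigar;
};

static PairAln align_pair_core(const std::string& q, const std::string& t,
                               int k, const AlphaEnc& enc, const Scorer& sc,
                               int xdrop, int band) {
  PairAln res;
  res.found = false;
  std::vector<Seed> seeds;
  find_seeds_core(q, t, k, enc, seeds);
  if (seeds.empty()) return res;
  std::vector<Hsp> hsps;
  hsps.reserve(seeds.size());
  for (const Seed& sd : seeds) hsps.push_back(extend_seed_core(q, t, sd, sc, xdrop));
  // dedupe identical intervals
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.qs != b.qs) return a.qs < b.qs;
    if (a.qe != b.qe) return a.qe < b.qe;
    if (a.ts != b.ts) return a.ts < b.ts;
    return a.te < b.te;
  });
  hsps.erase(std::unique(hsps.begin(), hsps.end(),
                         [](const Hsp& a, const Hsp& b) {
                           return a.qs == b.qs && a.qe == b.qe &&
                                  a.ts == b.ts && a.te == b.te;
                         }),
             hsps.end());
  std::vector<int> sel = chain_core(hsps);
  if (sel.empty()) return res;
  res.found = true;
  res.score = 0;
  res.matches = 0;
  res.length = 0;
  res.qs = hsps[sel.front()].qs;
  res.ts = hsps[sel.front()].ts;
  res.qe = hsps[sel.back()].qe;
  res.te = hsps[sel.back()].te;
  for (size_t si = 0; si < sel.size(); ++si) {
    const Hsp& h = hsps[sel[si]];
    if (si > 0) {
      const Hsp& prev = hsps[sel[si - 1]];
      std::string qseg = q.substr(prev.qe, h.qs - prev.qe);
      std::string tseg = t.substr(prev.te, h.ts - prev.te);
      std::vector<CigarOp> bridge;
      res.score += banded_core(qseg, tseg, sc, band, bridge);
      // count bridge columns & matches
      int qi = prev.qe, ti = prev.te;
      for (const CigarOp& o : bridge) {
        res.length += o.len;
        if (o.op == 'M') {
          for (int x = 0; x < o.len; ++x)
            if (q[qi + x] == t[ti + x]) ++res.matches;
          qi += o.len;
          ti += o.len;
        } else if (o.op == 'I') {
          qi += o.len;
        } else {
          ti += o.len;
        }
        cig_push(res.cigar, o.op, o.len);
      }
    }
    res.score += h.score;
    int len = h.qe - h.qs;
    res.length += len;
    for (int x = 0; x < len; ++x)
      if (q[h.qs + x] == t[h.ts + x]) ++res.matches;
    cig_push(res.cigar, 'M', len);
  }
  return res;
}

// Replace 'M' runs by '='/'X' runs using the two sequences.
static std::vector<CigarOp> extend_cigar(const std::vector<CigarOp>& cig,
                                         const std::string& q,
                                         const std::string& t, int qs, int ts) {
  std::vector<CigarOp> out;
  int qi = qs, ti = ts;
  for (const CigarOp& o : cig) {
    if (o.op == 'M') {
      for (int x = 0; x < o.len; ++x) {
        cig_push(out, q[qi] == t[ti] ? '=' : 'X');
        ++qi;
        ++ti;
      }
    } else {
      cig_push(out, o.op, o.len);
      if (o.op == 'I')
        qi += o.len;
      else
        ti += o.len;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string q, std::string t, int k, std::string alphabet,
                    IntegerMatrix scoreMat, CharacterVector letters, int open,
                    int ext, int xdrop, int band, bool extended) {
  AlphaEnc enc = make_enc(alphabet);
  Scorer sc = make_scorer(scoreMat, letters, open, ext);
  PairAln a = align_pair_core(q, t, k, enc, sc, xdrop, band);
  if (!a.found) return List::create(_["found"] = false);
  std::string cig = extended
                        ? cig_text(extend_cigar(a.cigar, q, t, a.qs, a.ts))
                        : cig_text(a.cigar);
  return List::create(
      _["found"] = true, _["qs"] = a.qs, _["qe"] = a.qe, _["ts"] = a.ts,
      _["te"] = a.te, _["score"] = a.score, _["matches"] = a.matches,
      _["length"] = a.length, _["cigar"] = cig);
}

// ---------------------------------------------------------------------------
// Search driver
// ---------------------------------------------------------------------------

static int count_gap_openings(const std::vector<CigarOp>& cig) {
  int g = 0;
  for (const CigarOp& o : cig)
    if (o.op == 'I' || o.op == 'D') ++g;
  return g;
}

// queries: plus-strand residues; rcqueries: reverse complements (parallel;
// only consulted when strandMode involves minus). strandMode: 0 plus,
// 1 minus, 2 both. Returns per-hit columns plus a per-query alignment count.
// [[Rcpp::export(name = ".cpp_search")]]
List cpp_search(SEXP xp_, CharacterVector queries, CharacterVector rcqueries,
                int strandMode, IntegerMatrix scoreMat, CharacterVector letters,
                int open, int ext, int xdrop, int band, double minIdentity,
                int maxAccepts, int maxRejects) {
  XPtr<KIndex> xp(xp_);
  const KIndex& ix = *xp;
  Scorer sc = make_scorer(scoreMat, letters, open, ext);
  std::vector<int> h_query, h_target, h_alen, h_mism, h_gapo;
  std::vector<int> h_qs, h_qe, h_ts, h_te;
  std::vector<double> h_ident;
  std::vector<std::string> h_cigar, h_strand;
  IntegerVector nAligned(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qplus = as<std::string>(queries[qi]);
    std::string qminus;
    if (strandMode != 0) qminus = as<std::string>(rcqueries[qi]);
    std::vector<Cand> cands;
    if (strandMode == 0 || strandMode == 2)
      count_shared_core(ix, qplus, 0, cands);
    if (strandMode == 1 || strandMode == 2)
      count_shared_core(ix, qminus, 1, cands);
    std::stable_sort(cands.begin(), cands.end(), cand_less);
    int accepts = 0, rejects = 0, aligned = 0;
    int Lq = (int)qplus.size();
    for (const Cand& cd : cands) {
      if (accepts >= maxAccepts || rejects >= maxRejects) break;
      const std::string& oq = (cd.strand == 0) ? qplus : qminus;
      const std::string& tg = ix.seqs[cd.target];
      ++aligned;
      PairAln a = align_pair_core(oq, tg, ix.k, ix.enc, sc, xdrop, band);
      if (!a.found) {
        ++rejects;
        continue;
      }
      double ident = a.length > 0 ? (double)a.matches / a.length : 0.0;
      if (ident >= minIdentity) {
        ++accepts;
        h_query.push_back(qi);
        h_target.push_back(cd.target);
        h_ident.push_back(ident);
        h_alen.push_back(a.length);
        int mcols = 0;
        for (const CigarOp& o : a.cigar)
          if (o.op == 'M') mcols += o.len;
        h_mism.push_back(mcols - a.matches);
        h_gapo.push_back(count_gap_openings(a.cigar));
        if (cd.strand == 0) {
          h_qs.push_back(a.qs + 1);
          h_qe.push_back(a.qe);
        } else {  // map back to the original (unreversed) query, 1-based
          h_qs.push_back(Lq - a.qe + 1);
          h_qe.push_back(Lq - a.qs);
        }
        h_ts.push_back(a.ts + 1);
        h_te.push_back(a.te);
        h_strand.push_back(cd.strand == 0 ? "+" : "-");
        h_cigar.push_back(cig_text(a.cigar));
      } else {
        ++rejects;
      }
    }
    nAligned[qi] = aligned;
  }
  return List::create(
      _["query"] = IntegerVector(h_query.begin(), h_query.end()),
      _["target"] = IntegerVector(h_target.begin(), h_target.end()),
      _["identity"] = NumericVector(h_ident.begin(), h_ident.end()),
      _["alen"] = IntegerVector(h_alen.begin(), h_alen.end()),
      _["mismatches"] = IntegerVector(h_mism.begin(), h_mism.end()),
      _["gap_openings"] = IntegerVector(h_gapo.begin(), h_gapo.end()),
      _["qstart"] = IntegerVector(h_qs.begin(), h_qs.end()),
      _["qend"] = IntegerVector(h_qe.begin(), h_qe.end()),
      _["tstart"] = IntegerVector(h_ts.begin(), h_ts.end()),
      _["tend"] = IntegerVector(h_te.begin(), h_te.end()),
      _["strand"] = CharacterVector(h_strand.begin(), h_strand.end()),
      _["cigar"] = CharacterVector(h_cigar.begin(), h_cigar.end()),
      _["n_aligned"] = nAligned);
}
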