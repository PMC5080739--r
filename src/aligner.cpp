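// Alignment core: maximal exact-match anchoring, affine-gap DP, score-aware
// local chaining with breaklen-bounded joins, and window-limited end extension.
// Coordinates are 0-based half-open throughout; the R layer converts for
// display. CIGAR ops: '=' match, 'X' mismatch, 'I' read-only base (gap in
// reference), 'D' reference-only base (gap in read). A gap run of length L
// scores gap_open + L * gap_extend.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}
static inline bool base_eq(char a, char b) {
  return base_ok(a) && a == b;
}

struct Anchor { int i, j, len; };

// k-mer index of the reference, built once per locus and reused across reads
struct RefIndex {
  int k;
  std::string seq;
  std::unordered_map<std::string, std::vector<int> > map;
};

// [[Rcpp::export]]
SEXP cpp_build_index(std::string ref, int k) {
  RefIndex* idx = new RefIndex();
  idx->k = k;
  idx->seq = ref;
  int m = ref.size();
  idx->map.reserve(m * 2);
  for (int j = 0; j + k <= m; ++j) {
    bool ok = true;
    for (int t = j; t < j + k; ++t) if (!base_ok(ref[t])) { ok = false; break; }
    if (ok) idx->map[ref.substr(j, k)].push_back(j);
  }
  XPtr<RefIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
bool cpp_index_ok(SEXP ptr, std::string ref, int k) {
  if (TYPEOF(ptr) != EXTPTRSXP || R_ExternalPtrAddr(ptr) == NULL) return false;
  XPtr<RefIndex> p(ptr);
  return p->k == k && p->seq == ref;
}

// All maximal exact matches of length >= k between read and ref (forward
// orientation). Each match is found once, at its left-maximal start. Non-ACGT
// characters never match, so N-runs produce no anchors.
static std::vector<Anchor> maximal_anchors(const std::string& read,
                                           const RefIndex& idx) {
  std::vector<Anchor> out;
  const std::string& ref = idx.seq;
  int k = idx.k;
  int n = read.size(), m = ref.size();
  if (n < k || m < k) return out;
  std::string kmer;
  for (int i = 0; i + k <= n; ++i) {
    bool ok = true;
    for (int t = i; t < i + k; ++t) if (!base_ok(read[t])) { ok = false; break; }
    if (!ok) continue;
    kmer.assign(read, i, k);
    auto hit = idx.map.find(kmer);
    if (hit == idx.map.end()) continue;
    for (int j : hit->second) {
      // left-maximal: cannot extend one base left
      if (i > 0 && j > 0 && base_eq(read[i - 1], ref[j - 1])) continue;
      int l = k;
      while (i + l < n && j + l < m && base_eq(read[i + l], ref[j + l])) ++l;
      out.push_back({i, j, l});
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_maximal_anchors(std::string read, SEXP index) {
  XPtr<RefIndex> p(index);
  std::vector<Anchor> a = maximal_anchors(read, *p);
  IntegerMatrix out(a.size(), 3);
  for (size_t r = 0; r < a.size(); ++r) {
    out(r, 0) = a[r].i; out(r, 1) = a[r].j; out(r, 2) = a[r].len;
  }
  colnames(out) = CharacterVector::create("read_start", "ref_start", "len");
  return out;
}

struct Scoring { int match, mismatch, gap_open, gap_extend; };

static std::string rle_encode(const std::string& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Global (Needleman-Wunsch/Gotoh) alignment of a (read side) vs b (ref side).
// Returns per-column op string (not RLE).
static int gotoh_global(const std::string& a, const std::string& b,
                        const Scoring& s, std::string& ops) {
  int n = a.size(), m = b.size();
  ops.clear();
  if (n == 0 && m == 0) return 0;
  if (n == 0) { ops.assign(m, 'D'); return s.gap_open + m * s.gap_extend; }
  if (m == 0) { ops.assign(n, 'I'); return s.gap_open + n * s.gap_extend; }
  static std::vector<int> M, Ix, Iy;
  static std::vector<char> tM, tIx, tIy;
  size_t sz = (size_t)(n + 1) * (m + 1);
  M.assign(sz, NEG); Ix.assign(sz, NEG); Iy.assign(sz, NEG);
  tM.assign(sz, 0); tIx.assign(sz, 0); tIy.assign(sz, 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = s.gap_open + i * s.gap_extend;
    tIx[at(i, 0)] = i == 1 ? 'M' : 'X';
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = s.gap_open + j * s.gap_extend;
    tIy[at(0, j)] = j == 1 ? 'M' : 'Y';
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = base_eq(a[i - 1], b[j - 1]) ? s.match : s.mismatch;
      int d = at(i - 1, j - 1);
      int bm = M[d], src = 'M';
      if (Ix[d] > bm) { bm = Ix[d]; src = 'X'; }
      if (Iy[d] > bm) { bm = Iy[d]; src = 'Y'; }
      M[at(i, j)] = bm == NEG ? NEG : bm + sub;
      tM[at(i, j)] = (char)src;
      int u = at(i - 1, j);
      int openx = M[u] == NEG ? NEG : M[u] + s.gap_open + s.gap_extend;
      int extx = Ix[u] == NEG ? NEG : Ix[u] + s.gap_extend;
      if (openx >= extx) { Ix[at(i, j)] = openx; tIx[at(i, j)] = 'M'; }
      else { Ix[at(i, j)] = extx; tIx[at(i, j)] = 'X'; }
      int l = at(i, j - 1);
      int openy = M[l] == NEG ? NEG : M[l] + s.gap_open + s.gap_extend;
      int exty = Iy[l] == NEG ? NEG : Iy[l] + s.gap_extend;
      if (openy >= exty) { Iy[at(i, j)] = openy; tIy[at(i, j)] = 'M'; }
      else { Iy[at(i, j)] = exty; tIy[at(i, j)] = 'Y'; }
    }
  }
  int e = at(n, m);
  int best = M[e]; char st = 'M';
  if (Ix[e] > best) { best = Ix[e]; st = 'X'; }
  if (Iy[e] > best) { best = Iy[e]; st = 'Y'; }
  // traceback
  int i = n, j = m; char cur = st;
  std::string rev;
  while (i > 0 || j > 0) {
    if (cur == 'M') {
      char src = tM[at(i, j)];
      rev += base_eq(a[i - 1], b[j - 1]) ? '=' : 'x';
      --i; --j; cur = src;
    } else if (cur == 'X') {
      char src = tIx[at(i, j)];
      rev += 'I'; --i; cur = src;
    } else {
      char src = tIy[at(i, j)];
      rev += 'D'; --j; cur = src;
    }
  }
  std::reverse(rev.begin(), rev.end());
  for (auto& c : rev) if (c == 'x') c = 'X';
  ops = rev;
  return best;
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend) {
  Scoring s{match, mismatch, gap_open, gap_extend};
  std::string ops;
  int sc = gotoh_global(a, b, s, ops);
  return List::create(_["score"] = sc, _["cigar"] = rle_encode(ops));
}

// Extension alignment: paths start at (0,0); the best-scoring M-cell anywhere
// in the (read_rem x window) matrix wins; no extension if best <= 0. The
// caller bounds the window by breaklen, which is what limits how far an
// extension may reach.
static int extend_dp(const std::string& a, const std::string& b,
                     const Scoring& s, std::string& ops, int& acons,
                     int& bcons) {
  int n = a.size(), m = b.size();
  ops.clear(); acons = 0; bcons = 0;
  if (n == 0 || m == 0) return 0;
  static std::vector<int> M, Ix, Iy;
  static std::vector<char> tM, tIx, tIy;
  size_t sz = (size_t)(n + 1) * (m + 1);
  M.assign(sz, NEG); Ix.assign(sz, NEG); Iy.assign(sz, NEG);
  tM.assign(sz, 0); tIx.assign(sz, 0); tIy.assign(sz, 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = s.gap_open + i * s.gap_extend;
    tIx[at(i, 0)] = i == 1 ? 'M' : 'X';
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = s.gap_open + j * s.gap_extend;
    tIy[at(0, j)] = j == 1 ? 'M' : 'Y';
  }
  int besti = 0, bestj = 0, best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = base_eq(a[i - 1], b[j - 1]) ? s.match : s.mismatch;
      int d = at(i - 1, j - 1);
      int bm = M[d], src = 'M';
      if (Ix[d] > bm) { bm = Ix[d]; src = 'X'; }
      if (Iy[d] > bm) { bm = Iy[d]; src = 'Y'; }
      M[at(i, j)] = bm == NEG ? NEG : bm + sub;
      tM[at(i, j)] = (char)src;
      if (M[at(i, j)] > best) { best = M[at(i, j)]; besti = i; bestj = j; }
      int u = at(i - 1, j);
      int openx = M[u] == NEG ? NEG : M[u] + s.gap_open + s.gap_extend;
      int extx = Ix[u] == NEG ? NEG : Ix[u] + s.gap_extend;
      if (openx >= extx) { Ix[at(i, j)] = openx; tIx[at(i, j)] = 'M'; }
      else { Ix[at(i, j)] = extx; tIx[at(i, j)] = 'X'; }
      int l = at(i, j - 1);
      int openy = M[l] == NEG ? NEG : M[l] + s.gap_open + s.gap_extend;
      int exty = Iy[l] == NEG ? NEG : Iy[l] + s.gap_extend;
      if (openy >= exty) { Iy[at(i, j)] = openy; tIy[at(i, j)] = 'M'; }
      else { Iy[at(i, j)] = exty; tIy[at(i, j)] = 'Y'; }
    }
  }
  if (best <= 0) return 0;
  int i = besti, j = bestj; char cur = 'M';
  std::string rev;
  while (i > 0 || j > 0) {
    if (cur == 'M') {
      char src = tM[at(i, j)];
      rev += base_eq(a[i - 1], b[j - 1]) ? '=' : 'x';
      --i; --j; cur = src;
    } else if (cur == 'X') {
      char src = tIx[at(i, j)];
      rev += 'I'; --i; cur = src;
    } else {
      char src = tIy[at(i, j)];
      rev += 'D'; --j; cur = src;
    }
  }
  std::reverse(rev.begin(), rev.end());
  for (auto& c : rev) if (c == 'x') c = 'X';
  ops = rev; acons = besti; bcons = bestj;
  return best;
}

// [[Rcpp::export]]
List cpp_extend(std::string a, std::string b, int match, int mismatch,
                int gap_open, int gap_extend) {
  Scoring s{match, mismatch, gap_open, gap_extend};
  std::string ops; int ac, bc;
  int sc = extend_dp(a, b, s, ops, ac, bc);
  return List::create(_["score"] = sc, _["cigar"] = rle_encode(ops),
                      _["read_consumed"] = ac, _["ref_consumed"] = bc);
}

static int score_ops(const std::string& ops, const Scoring& s) {
  int sc = 0; size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    int l = j - i;
    if (ops[i] == '=') sc += l * s.match;
    else if (ops[i] == 'X') sc += l * s.mismatch;
    else sc += s.gap_open + l * s.gap_extend;
    i = j;
  }
  return sc;
}

struct Edge { int a; int trim; int join_score; std::string join_ops; };

// Forward-orientation alignments of one read against the locus.
// [[Rcpp::export]]
DataFrame cpp_align_read(std::string read, SEXP index,
                         int breaklen, int match, int mismatch, int gap_open,
                         int gap_extend, int min_report) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  XPtr<RefIndex> pidx(index);
  const std::string& ref = pidx->seq;
  std::vector<Anchor> anch = maximal_anchors(read, *pidx);
  std::vector<int> rs, re, fs, fe, scov, nm, nx, ng;
  std::vector<std::string> cig;
  if (!anch.empty()) {
    if ((int)anch.size() > 2000) {
      std::sort(anch.begin(), anch.end(),
                [](const Anchor& a, const Anchor& b) { return a.len > b.len; });
      anch.resize(2000);
    }
    // topological order: ends strictly increase along any chain
    std::sort(anch.begin(), anch.end(), [](const Anchor& a, const Anchor& b) {
      if (a.i + a.len != b.i + b.len) return a.i + a.len < b.i + b.len;
      if (a.j + a.len != b.j + b.len) return a.j + a.len < b.j + b.len;
      return a.i < b.i;
    });
    int n = anch.size();
    std::vector<std::vector<Edge> > edges(n);
    for (int b = 0; b < n; ++b) {
      std::vector<std::pair<int, int> > cand; // (gap total, a)
      for (int a = 0; a < b; ++a) {
        const Anchor &A = anch[a], &B = anch[b];
        if (B.i < A.i || B.j < A.j) continue;
        if (B.i + B.len <= A.i + A.len || B.j + B.len <= A.j + A.len) continue;
        int rg = B.i - (A.i + A.len), fg = B.j - (A.j + A.len);
        if (rg > breaklen || fg > breaklen) continue;
        int d = std::max(0, std::max(-rg, -fg));
        if (B.len - d <= 0) continue;
        cand.push_back({std::max(rg, 0) + std::max(fg, 0), a});
      }
      std::sort(cand.begin(), cand.end());
      if (cand.size() > 30) cand.resize(30);
      for (auto& c : cand) {
        const Anchor &A = anch[c.second], &B = anch[b];
        int rg = B.i - (A.i + A.len), fg = B.j - (A.j + A.len);
        int d = std::max(0, std::max(-rg, -fg));
        std::string jo;
        int js = gotoh_global(read.substr(A.i + A.len, B.i + d - (A.i + A.len)),
                              ref.substr(A.j + A.len, B.j + d - (A.j + A.len)),
                              sc, jo);
        edges[b].push_back({c.second, d, js, jo});
      }
    }
    std::vector<bool> used(n, false);
    int rounds = 0;
    int remaining = n;
    while (remaining > 0 && rounds < 64) {
      ++rounds;
      std::vector<int> best(n, NEG), pred(n, -1), ptrim(n, 0);
      int gbest = NEG, gidx = -1;
      for (int b = 0; b < n; ++b) {
        if (used[b]) continue;
        best[b] = match * anch[b].len;
        for (auto& e : edges[b]) {
          if (used[e.a] || best[e.a] == NEG) continue;
          int v = best[e.a] + e.join_score + match * (anch[b].len - e.trim);
          if (v > best[b]) { best[b] = v; pred[b] = e.a; ptrim[b] = e.trim; }
        }
        if (best[b] > gbest) { gbest = best[b]; gidx = b; }
      }
      if (gidx < 0) break;
      // traceback the chain
      std::vector<int> chain;
      for (int x = gidx; x >= 0; x = pred[x]) chain.push_back(x);
      std::reverse(chain.begin(), chain.end());
      // build ops
      std::string ops;
      const Anchor& first = anch[chain[0]];
      int rstart = first.i, fstart = first.j;
      ops.append(first.len, '=');
      int rend = first.i + first.len, fend = first.j + first.len;
      for (size_t t = 1; t < chain.size(); ++t) {
        int b = chain[t], a = chain[t - 1];
        // find the edge used (pred/ptrim recorded only for the final pred;
        // chain links are exactly pred[] entries so look it up)
        const Edge* eu = nullptr;
        for (auto& e : edges[b]) if (e.a == a) { eu = &e; break; }
        ops += eu->join_ops;
        ops.append(anch[b].len - eu->trim, '=');
        rend = anch[b].i + anch[b].len;
        fend = anch[b].j + anch[b].len;
      }
      // end extensions (window bounded by breaklen)
      std::string lext, rext; int lac = 0, lbc = 0, rac = 0, rbc = 0;
      {
        std::string ra(read.rbegin() + (read.size() - rstart), read.rend());
        int w = std::min((int)rstart + breaklen, fstart);
        std::string rb(ref.rbegin() + (ref.size() - fstart),
                       ref.rbegin() + (ref.size() - fstart) + w);
        std::string o; extend_dp(ra, rb, sc, o, lac, lbc);
        std::reverse(o.begin(), o.end());
        lext = o;
      }
      {
        std::string ra = read.substr(rend);
        int w = std::min((int)ra.size() + breaklen, (int)ref.size() - fend);
        std::string rb = ref.substr(fend, w);
        extend_dp(ra, rb, sc, rext, rac, rbc);
      }
      auto emit = [&](int r0, int r1, int f0, int f1, const std::string& o) {
        int total = score_ops(o, sc);
        if (total < min_report) return;
        int m_ = 0, x_ = 0, g_ = 0;
        for (char c : o) {
          if (c == '=') ++m_;
          else if (c == 'X') ++x_;
          else ++g_;
        }
        rs.push_back(r0); re.push_back(r1); fs.push_back(f0); fe.push_back(f1);
        scov.push_back(total); nm.push_back(m_); nx.push_back(x_);
        ng.push_back(g_); cig.push_back(rle_encode(o));
      };
      emit(rstart, rend, fstart, fend, ops);
      if (lac + lbc + rac + rbc > 0)
        emit(rstart - lac, rend + rac, fstart - lbc, fend + rbc,
             lext + ops + rext);
      for (int x : chain)
        if (!used[x]) { used[x] = true; --remaining; }
    }
  }
  return DataFrame::create(
      _["read_start"] = rs, _["read_end"] = re, _["ref_start"] = fs,
      _["ref_end"] = fe, _["score"] = scov, _["n_match"] = nm,
      _["n_mismatch"] = nx, _["n_gapcols"] = ng, _["cigar"] = cig,
      _["stringsAsFactors"] = false);
}
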