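#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// Affine-gap pairwise alignment (3-state DP) with optional diagonal band.
// ia, ib: 1-based integer codes into the score matrix.
// Gap of length k costs go + k * ge.
// local = TRUE: Smith-Waterman (alignment starts and ends in match state);
// local = FALSE: Needleman-Wunsch over the full sequences.
// Band: cells with diag = j - i outside [dlo, dhi] are excluded; pass
// dlo > dhi for an unbanded run.
// [[Rcpp::export]]
List cpp_pair_align(IntegerVector ia, IntegerVector ib, NumericMatrix mat,
                    double go, double ge, bool local, int dlo, int dhi) {
  const int m = ia.size(), n = ib.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const bool banded = (dlo <= dhi);
  const int K = mat.nrow();
  std::vector<double> S((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) S[(size_t)i * K + j] = mat(i, j);

  const int lo = banded ? dlo : -m, hi = banded ? dhi : n;
  const size_t W = (size_t)(hi - lo + 1);
  // traceback: bits 0-1 pred of M (0=M,1=X,2=Y,3=start), 2-3 pred of X, 4-5 pred of Y
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  std::vector<double> Mprev(W, NEG_INF), Xprev(W, NEG_INF), Yprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF), Xcur(W, NEG_INF), Ycur(W, NEG_INF);

  double best = local ? 0.0 : NEG_INF;
  int bi = 0, bj = 0;

  // row 0
  for (int j = 0; j <= n; ++j) {
    int off = j - 0 - lo;
    if (off < 0 || off >= (int)W) continue;
    if (j == 0) { Mprev[off] = 0.0; tb[off] = 3; }
    else if (!local) {
      Yprev[off] = -go - ge * j;
      uint8_t yp = (j == 1) ? 0 : 2;
      tb[off] = 3 | (yp << 4);
    } else {
      Mprev[off] = NEG_INF; tb[off] = 3;
    }
  }

  const int openc = 1; // cost structure handled inline
  (void)openc;
  for (int i = 1; i <= m; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Xcur.begin(), Xcur.end(), NEG_INF);
    std::fill(Ycur.begin(), Ycur.end(), NEG_INF);
    const int a = ia[i - 1] - 1;
    int jlo = std::max(0, i + lo), jhi = std::min(n, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t off = (size_t)(j - i - lo);
      uint8_t cell = 0;
      // M state: from (i-1, j-1), same band offset in previous row
      double mM = NEG_INF, mX = NEG_INF, mY = NEG_INF;
      if (j >= 1) {
        // (i-1, j-1) has diag (j-1)-(i-1) = j-i -> same offset
        mM = Mprev[off]; mX = Xprev[off]; mY = Yprev[off];
      }
      double mbest = mM; uint8_t mp = 0;
      if (mX > mbest) { mbest = mX; mp = 1; }
      if (mY > mbest) { mbest = mY; mp = 2; }
      double sc = (j >= 1) ? S[(size_t)a * K + (ib[j - 1] - 1)] : NEG_INF;
      double Mval = (mbest <= NEG_INF / 2) ? NEG_INF : mbest + sc;
      if (local && sc > Mval) { Mval = sc; mp = 3; } // fresh start at this pair
      if (local && Mval < sc) { /* unreachable */ }
      if (!local && i >= 1 && j == 0) Mval = NEG_INF;
      cell |= mp;

      // X state: gap in b, from (i-1, j): diag j-(i-1) = off+1
      double xM = NEG_INF, xX = NEG_INF, xY = NEG_INF;
      if ((int)off + 1 < (int)W) {
        xM = Mprev[off + 1] - go - ge;
        xX = Xprev[off + 1] - ge;
        xY = Yprev[off + 1] - go - ge;
      }
      if (!local && j == 0 && i >= 1) { // column 0 init
        xM = (i == 1) ? -go - ge : NEG_INF;
        xX = (i > 1) ? -go - ge * i : NEG_INF;
        xY = NEG_INF;
      }
      double Xval = xM; uint8_t xp = 0;
      if (xX > Xval) { Xval = xX; xp = 1; }
      if (xY > Xval) { Xval = xY; xp = 2; }
      cell |= (xp << 2);

      // Y state: gap in a, from (i, j-1): diag (j-1)-i = off-1
      double yM = NEG_INF, yX = NEG_INF, yY = NEG_INF;
      if ((int)off - 1 >= 0) {
        yM = Mcur[off - 1] - go - ge;
        yX = Xcur[off - 1] - go - ge;
        yY = Ycur[off - 1] - ge;
      }
      double Yval = yM; uint8_t yp = 0;
      if (yX > Yval) { Yval = yX; yp = 1; }
      if (yY > Yval) { Yval = yY; yp = 2; }
      cell |= (yp << 4);

      Mcur[off] = Mval; Xcur[off] = Xval; Ycur[off] = Yval;
      tb[(size_t)i * W + off] = cell;
      if (local && Mval > best) { best = Mval; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int endState = 0;
  if (!local) {
    const int off = n - m - lo;
    if (off < 0 || off >= (int)W) stop("band does not contain the global end cell");
    double eM = Mprev[off], eX = Xprev[off], eY = Yprev[off];
    best = eM; endState = 0;
    if (eX > best) { best = eX; endState = 1; }
    if (eY > best) { best = eY; endState = 2; }
    bi = m; bj = n;
  }

  // traceback
  std::vector<int> pa, pb;
  if (local && best <= 0.0) {
    // empty local alignment
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["n_match"] = 0, _["n_cols"] = 0,
                        _["path_a"] = IntegerVector(0), _["path_b"] = IntegerVector(0));
  }
  int i = bi, j = bj, st = endState;
  int nmatch = 0;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    const size_t off = (size_t)(j - i - lo);
    uint8_t cell = tb[(size_t)i * W + off];
    if (st == 0) {
      uint8_t mp = cell & 3;
      pa.push_back(i); pb.push_back(j);
      if (ia[i - 1] == ib[j - 1]) ++nmatch;
      i -= 1; j -= 1;
      if (mp == 3) break; // local start (or global origin reached next loop)
      st = mp;
    } else if (st == 1) {
      uint8_t xp = (cell >> 2) & 3;
      pa.push_back(i); pb.push_back(0);
      i -= 1; st = xp;
    } else {
      uint8_t yp = (cell >> 4) & 3;
      pa.push_back(0); pb.push_back(j);
      j -= 1; st = yp;
    }
    if (local && st == 0 && (i == 0 || j == 0)) break;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  int a0 = 0, a1 = 0, b0 = 0, b1 = 0;
  for (size_t q = 0; q < pa.size(); ++q) {
    if (pa[q] > 0) { if (a0 == 0) a0 = pa[q]; a1 = pa[q]; }
    if (pb[q] > 0) { if (b0 == 0) b0 = pb[q]; b1 = pb[q]; }
  }
  return List::create(_["score"] = best, _["a_start"] = a0, _["a_end"] = a1,
                      _["b_start"] = b0, _["b_end"] = b1,
                      _["n_match"] = nmatch, _["n_cols"] = (int)pa.size(),
                      _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

// Profile-profile global affine alignment. Profiles are K x L frequency
// matrices; column score = fA' * mat * fB. Returns the merge path.
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix profA, NumericMatrix profB,
                       NumericMatrix mat, double go, double ge) {
  const int K = profA.nrow(), m = profA.ncol(), n = profB.ncol();
  if (profB.nrow() != K || mat.nrow() != K || mat.ncol() != K)
    stop("profile/matrix dimension mismatch");
  // SB = mat %*% profB  (K x n)
  std::vector<double> SB((size_t)K * n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int r = 0; r < K; ++r) {
      double acc = 0.0;
      for (int c = 0; c < K; ++c) acc += mat(r, c) * profB(c, j);
      SB[(size_t)j * K + r] = acc;
    }
  std::vector<double> Mp(n + 1, NEG_INF), Xp(n + 1, NEG_INF), Yp(n + 1, NEG_INF);
  std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  Mp[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    Yp[j] = -go - ge * j;
    tb[j] = 3 | (((j == 1) ? 0 : 2) << 4);
  }
  tb[0] = 3;
  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Xc.begin(), Xc.end(), NEG_INF);
    std::fill(Yc.begin(), Yc.end(), NEG_INF);
    Xc[0] = -go - ge * i;
    tb[(size_t)i * (n + 1)] = 3 | (((i == 1) ? 0 : 1) << 2);
    for (int j = 1; j <= n; ++j) {
      uint8_t cell = 0;
      double sc = 0.0;
      for (int r = 0; r < K; ++r) sc += profA(r, i - 1) * SB[(size_t)(j - 1) * K + r];
      double mbest = Mp[j - 1]; uint8_t mp = 0;
      if (Xp[j - 1] > mbest) { mbest = Xp[j - 1]; mp = 1; }
      if (Yp[j - 1] > mbest) { mbest = Yp[j - 1]; mp = 2; }
      Mc[j] = (mbest <= NEG_INF / 2) ? NEG_INF : mbest + sc;
      cell |= mp;
      double xb = Mp[j] - go - ge; uint8_t xp = 0;
      if (Xp[j] - ge > xb) { xb = Xp[j] - ge; xp = 1; }
      if (Yp[j] - go - ge > xb) { xb = Yp[j] - go - ge; xp = 2; }
      Xc[j] = xb; cell |= (xp << 2);
      double yb = Mc[j - 1] - go - ge; uint8_t yp = 0;
      if (Xc[j - 1] - go - ge > yb) { yb = Xc[j - 1] - go - ge; yp = 1; }
      if (Yc[j - 1] - ge > yb) { yb = Yc[j - 1] - ge; yp = 2; }
      Yc[j] = yb; cell |= (yp << 4);
      tb[(size_t)i * (n + 1) + j] = cell;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double best = Mp[n]; int st = 0;
  if (Xp[n] > best) { best = Xp[n]; st = 1; }
  if (Yp[n] > best) { best = Yp[n]; st = 2; }
  std::vector<int> pa, pb;
  int i = m, j = n;
  while (!(i == 0 && j == 0)) {
    uint8_t cell = tb[(size_t)i * (n + 1) + j];
    if (st == 0) { pa.push_back(i); pb.push_back(j); st = cell & 3; i--; j--; if (st == 3) st = 0; }
    else if (st == 1) { pa.push_back(i); pb.push_back(0); uint8_t xp = (cell >> 2) & 3; i--; st = xp; }
    else { pa.push_back(0); pb.push_back(j); uint8_t yp = (cell >> 4) & 3; j--; st = yp; }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = best, _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void collect_kmers(const std::string &s, int k,
                          std::vector<std::pair<uint64_t, int> > &out) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(std::make_pair(key, i - k + 2)); // 1-based start
  }
}

// All pairs of identical k-mers in one sequence whose start-to-start spacing
// lies in [dmin, dmax]; direct orientation only. Returns 2-column matrix
// (pos1, pos2), 1-based starts, pos1 < pos2.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_pairs_self(std::string seq, int k, int dmin, int dmax) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::vector<std::pair<uint64_t, int> > km;
  collect_kmers(seq, k, km);
  std::sort(km.begin(), km.end());
  std::vector<int> p1, p2;
  size_t i = 0;
  while (i < km.size()) {
    size_t j = i;
    while (j < km.size() && km[j].first == km[i].first) ++j;
    // positions km[i..j-1] ascending
    for (size_t a = i; a + 1 < j; ++a) {
      for (size_t b = a + 1; b < j; ++b) {
        int d = km[b].second - km[a].second;
        if (d > dmax) break;
        if (d >= dmin) { p1.push_back(km[a].second); p2.push_back(km[b].second); }
      }
    }
    i = j;
  }
  IntegerMatrix out(p1.size(), 2);
  for (size_t r = 0; r < p1.size(); ++r) { out(r, 0) = p1[r]; out(r, 1) = p2[r]; }
  return out;
}

// generic 5-bit packing over A-Z (any residue alphabet), k <= 12
static void collect_kmers_gen(const std::string &s, int k,
                              std::vector<std::pair<uint64_t, int> > &out) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t key = 0, mask = (1ULL << (5 * k)) - 1;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    char c = s[i];
    if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
    if (c < 'A' || c > 'Z' || c == 'X' || c == 'N') { run = 0; key = 0; continue; }
    key = ((key << 5) | (uint64_t)(c - 'A')) & mask;
    if (++run >= k) out.push_back(std::make_pair(key, i - k + 2));
  }
}

// All exact k-mer matches between two sequences over an arbitrary residue
// alphabet (case-insensitive; X and N never seed). Returns (qpos, spos).
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_matches_gen(std::string query, std::string subject,
                                   int k) {
  if (k < 1 || k > 12) stop("k must be in 1..12");
  std::vector<std::pair<uint64_t, int> > kq, ks;
  collect_kmers_gen(query, k, kq);
  collect_kmers_gen(subject, k, ks);
  std::sort(kq.begin(), kq.end());
  std::sort(ks.begin(), ks.end());
  std::vector<int> qp, sp;
  size_t i = 0, j = 0;
  while (i < kq.size() && j < ks.size()) {
    if (kq[i].first < ks[j].first) ++i;
    else if (ks[j].first < kq[i].first) ++j;
    else {
      size_t i2 = i, j2 = j;
      while (i2 < kq.size() && kq[i2].first == kq[i].first) ++i2;
      while (j2 < ks.size() && ks[j2].first == kq[i].first) ++j2;
      for (size_t a = i; a < i2; ++a)
        for (size_t b = j; b < j2; ++b) { qp.push_back(kq[a].second); sp.push_back(ks[b].second); }
      i = i2; j = j2;
    }
  }
  IntegerMatrix out(qp.size(), 2);
  for (size_t r = 0; r < qp.size(); ++r) { out(r, 0) = qp[r]; out(r, 1) = sp[r]; }
  return out;
}

// All exact k-mer matches between query and subject. Returns 2-column matrix
// (qpos, spos), 1-based starts.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_matches(std::string query, std::string subject, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  std::vector<std::pair<uint64_t, int> > kq, ks;
  collect_kmers(query, k, kq);
  collect_kmers(subject, k, ks);
  std::sort(kq.begin(), kq.end());
  std::sort(ks.begin(), ks.end());
  std::vector<int> qp, sp;
  size_t i = 0, j = 0;
  while (i < kq.size() && j < ks.size()) {
    if (kq[i].first < ks[j].first) ++i;
    else if (ks[j].first < kq[i].first) ++j;
    else {
      size_t i2 = i, j2 = j;
      while (i2 < kq.size() && kq[i2].first == kq[i].first) ++i2;
      while (j2 < ks.size() && ks[j2].first == kq[i].first) ++j2;
      for (size_t a = i; a < i2; ++a)
        for (size_t b = j; b < j2; ++b) { qp.push_back(kq[a].second); sp.push_back(ks[b].second); }
      i = i2; j = j2;
    }
  }
  IntegerMatrix out(qp.size(), 2);
  for (size_t r = 0; r < qp.size(); ++r) { out(r, 0) = qp[r]; out(r, 1) = sp[r]; }
  return out;
}
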