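#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// N (or any non-ACGT character) never counts as a match.
static inline bool base_match(char x, char y) {
  if (x != y) return false;
  return x == 'A' || x == 'C' || x == 'G' || x == 'T';
}

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Returns matches and aligned columns excluding terminal gap runs.
// [[Rcpp::export]]
List nw_global_cpp(std::string a, std::string b,
                   double match = 1.0, double mismatch = -1.0,
                   double gap = 2.0) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 1 diag, 2 up, 3 left
  for (int j = 1; j <= m; ++j) { prev[j] = -gap * j; tb[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -gap * i;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double sup   = prev[j] - gap;
      double sleft = cur[j - 1] - gap;
      double best = sdiag; uint8_t d = 1;
      if (sup > best)   { best = sup;   d = 2; }
      if (sleft > best) { best = sleft; d = 3; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = d;
    }
    std::swap(prev, cur);
  }
  const double score = prev[m];
  // traceback; ops recorded from alignment end to start
  std::vector<uint8_t> ops;
  ops.reserve(n + m);
  int i = n, j = m, matches = 0;
  while (i > 0 || j > 0) {
    uint8_t d = tb[(size_t)i * (m + 1) + j];
    ops.push_back(d);
    if (d == 1) { if (base_match(a[i - 1], b[j - 1])) ++matches; --i; --j; }
    else if (d == 2) --i;
    else --j;
  }
  // trim terminal gap columns (runs of non-diagonal ops at either end)
  int lo = 0, hi = (int)ops.size() - 1;
  while (lo <= hi && ops[lo] != 1) ++lo;   // alignment end
  while (hi >= lo && ops[hi] != 1) --hi;   // alignment start
  const int columns = (lo > hi) ? 0 : (hi - lo + 1);
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = columns,
                      _["align_length"] = (int)ops.size());
}

// Banded local (Smith-Waterman) alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_extend.
// Band restricts computed cells to band_lo <= j - i <= band_hi
// (i indexes a, j indexes b, both 1-based DP coordinates); a band wide
// enough to cover [-n, m] makes the computation exact/unbanded.
// [[Rcpp::export]]
List sw_band_cpp(std::string a, std::string b,
                 double match = 1.0, double mismatch = -1.0,
                 double gap_open = 5.0, double gap_extend = 1.0,
                 int band_lo = NA_INTEGER, int band_hi = NA_INTEGER) {
  const int n = a.size(), m = b.size();
  if (band_lo == NA_INTEGER) band_lo = -n;
  if (band_hi == NA_INTEGER) band_hi = m;
  if (band_lo < -n) band_lo = -n;
  if (band_hi > m)  band_hi = m;
  if (band_hi < band_lo)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  const int W = band_hi - band_lo + 1;
  const double NEG = -1e18, go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> Hprev(W, NEG), Hcur(W, NEG), Eprev(W, NEG), Ecur(W, NEG),
      Fprev(W, NEG), Fcur(W, NEG);
  // traceback: tbH 0 stop, 1 diag, 2 E(gap in a), 3 F(gap in b);
  // tbE/tbF: 1 = extend, 0 = open from H
  std::vector<uint8_t> tbH((size_t)(n + 1) * W, 0), tbE((size_t)(n + 1) * W, 0),
      tbF((size_t)(n + 1) * W, 0);
  // row 0
  for (int c = 0; c < W; ++c) {
    int j = 0 + band_lo + c;
    if (j >= 0 && j <= m) Hprev[c] = 0.0;
  }
  double best = 0.0; int besti = -1, bestc = -1;
  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    for (int c = 0; c < W; ++c) {
      const int j = i + band_lo + c;
      if (j < 0 || j > m) continue;
      if (j == 0) { Hcur[c] = 0.0; continue; }
      const size_t off = (size_t)i * W + c;
      // E: gap in a, consume b; predecessor (i, j-1) -> same row, c-1
      double e = NEG;
      if (c - 1 >= 0) {
        double open = Hcur[c - 1] - go, ext = Ecur[c - 1] - ge;
        if (open >= ext) { e = open; tbE[off] = 0; }
        else             { e = ext;  tbE[off] = 1; }
      }
      Ecur[c] = e;
      // F: gap in b, consume a; predecessor (i-1, j) -> previous row, c+1
      double f = NEG;
      if (c + 1 < W) {
        double open = Hprev[c + 1] - go, ext = Fprev[c + 1] - ge;
        if (open >= ext) { f = open; tbF[off] = 0; }
        else             { f = ext;  tbF[off] = 1; }
      }
      Fcur[c] = f;
      // H
      double diag = NEG;
      if (Hprev[c] > NEG / 2)
        diag = Hprev[c] + (base_match(a[i - 1], b[j - 1]) ? match : mismatch);
      double h = 0.0; uint8_t d = 0;
      if (diag > h) { h = diag; d = 1; }
      if (e > h)    { h = e;    d = 2; }
      if (f > h)    { h = f;    d = 3; }
      Hcur[c] = h; tbH[off] = d;
      if (h > best) { best = h; besti = i; bestc = c; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (besti < 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  // traceback
  int i = besti, c = bestc;
  int state = 0; // 0 = H, 1 = E, 2 = F
  int matches = 0, columns = 0;
  const int a_end = besti, b_end = besti + band_lo + bestc;
  for (;;) {
    const size_t off = (size_t)i * W + c;
    if (state == 0) {
      uint8_t d = tbH[off];
      if (d == 0) break;
      if (d == 1) {
        int j = i + band_lo + c;
        if (base_match(a[i - 1], b[j - 1])) ++matches;
        ++columns; --i; // c unchanged on diagonal move
      } else if (d == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E at (i,j): came from (i, j-1)
      uint8_t d = tbE[off];
      ++columns; --c;
      state = (d == 1) ? 1 : 0;
    } else { // F at (i,j): came from (i-1, j)
      uint8_t d = tbF[off];
      ++columns; --i; ++c;
      state = (d == 1) ? 2 : 0;
    }
  }
  const int a_start = i, b_start = i + band_lo + c;
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = columns,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}

static inline int enc(char x) {
  switch (x) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Exact shared k-mers between query and target (forward orientation).
// Returns a 2-column matrix of 0-based (query_pos, target_pos) pairs.
// [[Rcpp::export]]
IntegerMatrix kmer_hits_cpp(std::string query, std::string target, int k,
                            int max_hits = 5000000) {
  const int nq = query.size(), nt = target.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  if (nq >= k) {
    uint64_t key = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int p = 0; p < nq; ++p) {
      int e = enc(query[p]);
      if (e < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)e) & mask;
      if (++valid >= k) idx[key].push_back(p - k + 1);
    }
  }
  std::vector<int> qpos, tpos;
  if (nt >= k && !idx.empty()) {
    uint64_t key = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int p = 0; p < nt; ++p) {
      int e = enc(target[p]);
      if (e < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)e) & mask;
      if (++valid >= k) {
        auto it = idx.find(key);
        if (it != idx.end()) {
          for (int q : it->second) {
            qpos.push_back(q); tpos.push_back(p - k + 1);
            if ((int)qpos.size() >= max_hits) goto done;
          }
        }
      }
    }
  }
done:
  IntegerMatrix out(qpos.size(), 2);
  for (size_t r = 0; r < qpos.size(); ++r) { out(r, 0) = qpos[r]; out(r, 1) = tpos[r]; }
  colnames(out) = CharacterVector::create("qpos", "tpos");
  return out;
}
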