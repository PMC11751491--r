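#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Banded dynamic-programming alignment with affine gaps over 2-bit base codes
// (-1 = N, always scored as a mismatch). A gap of length L costs
// gap_open + L * gap_extend. The band is expressed in diagonals: cells with
// j - i in [min(0, n-m) - band, max(0, n-m) + band] are computed, so the band
// always contains both corners and band >= m + n reduces to the full matrix.

static const int NEG = INT32_MIN / 4;

struct AlnResult {
  int score, a_begin, a_end, b_begin, b_end;
  int n_match, n_mismatch, n_ins, n_del;
  std::string cigar;
};

static std::string rle_cigar(const std::string &ops_rev) {
  // ops_rev collected from traceback (end -> start); reverse then run-length
  std::string out;
  int n = (int) ops_rev.size();
  int i = n - 1;
  while (i >= 0) {
    char op = ops_rev[i];
    int j = i;
    while (j >= 0 && ops_rev[j] == op) --j;
    out += std::to_string(i - j);
    out += op;
    i = j;
  }
  return out;
}

static AlnResult banded_align(const int *a, int m, const int *b, int n,
                              int match, int mismatch, int gapo, int gape,
                              int band, bool local) {
  int dlo = std::min(0, n - m) - band;
  int dhi = std::max(0, n - m) + band;
  if (dlo < -m) dlo = -m;
  if (dhi > n) dhi = n;
  int W = dhi - dlo + 1;

  std::vector<int> Hprev(W, NEG), Fprev(W, NEG), Hcur(W, NEG), Fcur(W, NEG),
                   Ecur(W, NEG);
  std::vector<uint8_t> tb((size_t) (m + 1) * W, 0);
  // tb bits 0-1: H source (0 stop, 1 diag, 2 E/del, 3 F/ins)
  // bit 2: E extends E; bit 3: F extends F

  int best = local ? 0 : NEG, best_i = 0, best_j = 0;

  // row 0
  {
    int jhi = std::min(n, dhi);
    for (int j = 0; j <= jhi; ++j) {
      int idx = j - dlo;
      if (local) {
        Hprev[idx] = 0;
      } else {
        Hprev[idx] = (j == 0) ? 0 : -(gapo + gape * j);
        tb[idx] = (j == 0) ? 0 : 2;  // leading deletion chain
        if (j > 1) tb[idx] |= 4;
      }
    }
  }

  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i + dlo), jhi = std::min(n, i + dhi);
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    for (int j = jlo; j <= jhi; ++j) {
      int idx = j - i - dlo;
      uint8_t t = 0;
      // E: gap in a (consume b), from the left neighbour in this row
      int e = NEG;
      bool eext = false;
      if (j > jlo && idx - 1 >= 0) {
        int e_open = Hcur[idx - 1] - gapo - gape;
        int e_ext = Ecur[idx - 1] - gape;
        e = std::max(e_open, e_ext);
        eext = e_ext > e_open;
      } else if (j == 0) {
        e = NEG;
      } else if (!local && j > 0 && idx - 1 < 0) {
        e = NEG;  // left of band
      }
      // F: gap in b (consume a), from the cell above
      int f = NEG;
      bool fext = false;
      if (idx + 1 < W) {
        int f_open = Hprev[idx + 1] - gapo - gape;
        int f_ext = Fprev[idx + 1] - gape;
        f = std::max(f_open, f_ext);
        fext = f_ext > f_open;
      }
      // diagonal
      int diag = NEG;
      if (j > 0) {
        int s = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? match : -mismatch;
        diag = Hprev[idx] + s;
      }
      int h = std::max(diag, std::max(e, f));
      if (h == diag && diag > NEG / 2) t |= 1;
      else if (h == e) t |= 2;
      else if (h == f) t |= 3;
      if (local && h <= 0) { h = 0; t &= ~3; }
      if (eext) t |= 4;
      if (fext) t |= 8;
      Hcur[idx] = h;
      Ecur[idx] = e;
      Fcur[idx] = f;
      tb[(size_t) i * W + idx] = t;
      if (local && h > best) { best = h; best_i = i; best_j = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  AlnResult res;
  res.n_match = res.n_mismatch = res.n_ins = res.n_del = 0;
  int i, j;
  if (local) {
    res.score = best;
    i = best_i; j = best_j;
    res.a_end = i; res.b_end = j;
  } else {
    int idx_end = n - m - dlo;
    res.score = Hprev[idx_end];
    i = m; j = n;
    res.a_end = m; res.b_end = n;
  }

  std::string ops;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t) i * W + (j - i - dlo)];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) {
        if (local) break;
        // outside stored paths (global corners): finish with pure gaps
        if (i == 0 && j > 0) { ops += 'D'; ++res.n_del; --j; continue; }
        if (j == 0 && i > 0) { ops += 'I'; ++res.n_ins; --i; continue; }
        break;
      }
      if (src == 1) {
        ops += 'M';
        if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++res.n_match;
        else ++res.n_mismatch;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops += 'D'; ++res.n_del;
      state = (t & 4) ? 1 : 0;
      --j;
      if (j == 0 && state == 1) state = 0;
    } else {
      ops += 'I'; ++res.n_ins;
      state = (t & 8) ? 2 : 0;
      --i;
      if (i == 0 && state == 2) state = 0;
    }
  }
  res.a_begin = i;
  res.b_begin = j;
  res.cigar = rle_cigar(ops);
  return res;
}

// [[Rcpp::export]]
List banded_align_cpp(IntegerVector a, IntegerVector b, int match, int mismatch,
                      int gap_open, int gap_extend, int band, bool local) {
  if (a.size() == 0) stop("empty query sequence");
  if (band < 1) stop("band must be >= 1");
  int m = (int) a.size(), n = (int) b.size();
  const int *ap = &a[0];
  const int *bp = n > 0 ? &b[0] : nullptr;
  AlnResult r = banded_align(ap, m, bp, n, match, mismatch, gap_open,
                             gap_extend, band, local);
  return List::create(
    _["score"] = r.score, _["cigar"] = r.cigar,
    _["a_begin"] = r.a_begin, _["a_end"] = r.a_end,
    _["b_begin"] = r.b_begin, _["b_end"] = r.b_end,
    _["n_match"] = r.n_match, _["n_mismatch"] = r.n_mismatch,
    _["n_ins"] = r.n_ins, _["n_del"] = r.n_del);
}

// Unit-cost edit distance by the standard two-row dynamic program.
// [[Rcpp::export]]
int levenshtein_cpp(std::string a, std::string b) {
  int m = (int) a.size(), n = (int) b.size();
  if (m == 0) return n;
  if (n == 0) return m;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
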