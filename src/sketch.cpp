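#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3; ambiguous (N) is -1 at the R boundary.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return -1;
    default: return -2;
  }
}

// Thomas Wang's 64-bit integer finalizer, masked to the 2k-bit domain at every
// step so it stays invertible on [0, 4^k).
static inline uint64_t wang_hash(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

// [[Rcpp::export]]
IntegerVector encode_bases_cpp(std::string seq) {
  R_xlen_t n = (R_xlen_t) seq.size();
  IntegerVector codes(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c == -2)
      stop("invalid base '%c' at position %d (alphabet is A,C,G,T,N)",
           seq[i], (int) (i + 1));
    codes[i] = c;
  }
  return codes;
}

// [[Rcpp::export]]
std::string decode_bases_cpp(IntegerVector codes) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  std::string out(codes.size(), 'N');
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    if (codes[i] >= 0) out[i] = tab[codes[i]];
  return out;
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string seq) {
  std::string out(seq.size(), 'N');
  R_xlen_t n = (R_xlen_t) seq.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    char c = seq[n - 1 - i], o;
    switch (c) {
      case 'A': o = 'T'; break; case 'a': o = 'T'; break;
      case 'C': o = 'G'; break; case 'c': o = 'G'; break;
      case 'G': o = 'C'; break; case 'g': o = 'C'; break;
      case 'T': o = 'A'; break; case 't': o = 'A'; break;
      default:  o = 'N';
    }
    out[i] = o;
  }
  return out;
}

// [[Rcpp::export]]
double hash_kmer_cpp(double packed, int k) {
  if (k < 1 || k > 28) stop("k must be in [1, 28]");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = (uint64_t) packed;
  if (packed < 0 || key > mask) stop("packed k-mer out of [0, 4^k)");
  return (double) wang_hash(key, mask);
}

struct MiniOut {
  std::vector<double> hash;
  std::vector<int> pos, span, strand;
};

// One maximal N-free run of the (already patterned) code sequence.
// codes/origin are offset by `off` into the full arrays; len is the run length.
static void minimize_run(const int *codes, const int *origin, int len,
                         int k, int w, uint64_t mask, MiniOut &out) {
  if (len < k) return;
  int nk = len - k + 1;
  std::vector<uint64_t> h((size_t) nk);
  std::vector<uint8_t> strand((size_t) nk), valid((size_t) nk, 1);
  uint64_t fwd = 0, rev = 0;
  int shift = 2 * (k - 1);
  for (int i = 0; i < len; ++i) {
    uint64_t c = (uint64_t) codes[i];
    fwd = ((fwd << 2) | c) & mask;
    rev = (rev >> 2) | ((3ULL - c) << shift);
    if (i >= k - 1) {
      int j = i - k + 1;
      if (fwd < rev)      { h[j] = wang_hash(fwd, mask); strand[j] = 0; }
      else if (rev < fwd) { h[j] = wang_hash(rev, mask); strand[j] = 1; }
      else valid[j] = 0;  // palindromic k-mer: strand-ambiguous, skipped
    }
  }
  // windows of w consecutive k-mers; if fewer than w k-mers exist, a single
  // window covering all of them is used
  int nw = (nk >= w) ? (nk - w + 1) : 1;
  int wlen = (nk >= w) ? w : nk;
  std::vector<uint8_t> emitted((size_t) nk, 0);
  for (int ws = 0; ws < nw; ++ws) {
    uint64_t best = ~0ULL;
    bool any = false;
    for (int j = ws; j < ws + wlen; ++j)
      if (valid[j] && (!any || h[j] < best)) { best = h[j]; any = true; }
    if (!any) continue;
    for (int j = ws; j < ws + wlen; ++j) {
      if (valid[j] && h[j] == best && !emitted[j]) {
        emitted[j] = 1;
        out.hash.push_back((double) h[j]);
        out.pos.push_back(origin[j]);
        out.span.push_back(origin[j + k - 1] - origin[j] + 1);
        out.strand.push_back(strand[j]);
      }
    }
  }
}

// Double-strand (w,k)-minimizers of a patterned sequence. `codes` holds the
// included bases (-1 for N), `origin` their original 0-based coordinates.
// Positions reported are original coordinates; span is the original-coordinate
// width of the k included bases.
// [[Rcpp::export]]
DataFrame extract_minimizers_cpp(IntegerVector codes, IntegerVector origin,
                                 int k, int w) {
  if (k < 1 || k > 28) stop("k must be in [1, 28]");
  if (w < 1) stop("w must be >= 1");
  if (codes.size() != origin.size()) stop("codes/origin length mismatch");
  uint64_t mask = (1ULL << (2 * k)) - 1;
  MiniOut out;
  int n = (int) codes.size();
  int run_start = 0;
  for (int i = 0; i <= n; ++i) {
    if (i == n || codes[i] < 0) {
      if (i > run_start)
        minimize_run(&codes[0] + run_start, &origin[0] + run_start,
                     i - run_start, k, w, mask, out);
      run_start = i + 1;
    }
  }
  return DataFrame::create(_["hash"] = wrap(out.hash),
                           _["pos"] = wrap(out.pos),
                           _["span"] = wrap(out.span),
                           _["strand"] = wrap(out.strand));
}

// Canonical hashes of every overlapping k-mer (benchmark "All Seeds" mode).
// Palindromic k-mers keep their (strand-shared) hash. N splits runs.
// [[Rcpp::export]]
NumericVector extract_all_seeds_cpp(IntegerVector codes, int k) {
  if (k < 1 || k > 28) stop("k must be in [1, 28]");
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<double> out;
  int n = (int) codes.size();
  int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int runlen = 0;
  for (int i = 0; i < n; ++i) {
    if (codes[i] < 0) { runlen = 0; continue; }
    uint64_t c = (uint64_t) codes[i];
    fwd = ((fwd << 2) | c) & mask;
    rev = (rev >> 2) | ((3ULL - c) << shift);
    if (++runlen >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out.push_back((double) wang_hash(canon, mask));
    }
  }
  return wrap(out);
}

// Spaced seeds: for every start position, sample the bases under the 1s of
// `mask` (a 0/1 integer vector defining the seed span) and hash the packed
// concatenation canonically. Windows whose sampled bases include an N are
// skipped; the seed count otherwise depends only on the span.
// [[Rcpp::export]]
NumericVector extract_spaced_seeds_cpp(IntegerVector codes, IntegerVector mask) {
  int span = (int) mask.size();
  std::vector<int> ones;
  for (int i = 0; i < span; ++i) {
    if (mask[i] != 0 && mask[i] != 1) stop("mask must be over {0,1}");
    if (mask[i] == 1) ones.push_back(i);
  }
  int kk = (int) ones.size();
  if (kk < 1 || kk > 28) stop("mask weight must be in [1, 28]");
  uint64_t hmask = (1ULL << (2 * kk)) - 1;
  int n = (int) codes.size();
  std::vector<double> out;
  for (int s = 0; s + span <= n; ++s) {
    uint64_t fwd = 0, rev = 0;
    bool ok = true;
    for (int j = 0; j < kk; ++j) {
      int c = codes[s + ones[j]];
      if (c < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t) c;
      rev |= (3ULL - (uint64_t) c) << (2 * j);
    }
    if (!ok) continue;
    uint64_t canon = fwd < rev ? fwd : rev;
    out.push_back((double) wang_hash(canon, hmask));
  }
  return wrap(out);
}
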