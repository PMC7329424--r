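#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Feature values must round-trip exactly through R doubles, so the 64-bit
// mix is truncated to the low 53 bits (the double mantissa width).
static const uint64_t FEATURE_MASK = (1ULL << 53) - 1;

// splitmix64 finalizer: a fixed, well-mixed 64-bit integer hash.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline uint64_t h1_hash(uint64_t canonical_code) {
  return mix64(canonical_code) & FEATURE_MASK;
}

// 2-bit base code; -1 for anything outside {A,C,G,T} (case-insensitive).
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical code of the k-mer starting at p: min(forward, reverse-complement)
// of the 2-bit packing (first base in the highest bits). Returns false if the
// k-mer contains a non-ACGT base.
static bool canonical_code_at(const char* seq, int p, int k, uint64_t& out) {
  uint64_t fwd = 0, rc = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bit(seq[p + i]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rc |= ((uint64_t)(3 - b)) << (2 * i);
  }
  out = fwd < rc ? fwd : rc;
  return true;
}

// Sketch of one window [start, end): distinct h1 values of all valid k-mers,
// ascending, at most s of them.
static std::vector<uint64_t> sketch_span(const char* seq, int start, int end,
                                         int k, int s) {
  std::vector<uint64_t> h;
  for (int p = start; p + k <= end; ++p) {
    uint64_t code;
    if (canonical_code_at(seq, p, k, code)) h.push_back(h1_hash(code));
  }
  std::sort(h.begin(), h.end());
  h.erase(std::unique(h.begin(), h.end()), h.end());
  if ((int)h.size() > s) h.resize(s);
  return h;
}

// [[Rcpp::export]]
NumericVector cpp_encode_canonical(CharacterVector kmers) {
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(kmers[i]);
    int k = LENGTH(kmers[i]);
    if (k < 1 || k > 26)
      stop("k-mer length must be between 1 and 26 for exact double encoding");
    uint64_t code;
    out[i] = canonical_code_at(s, 0, k, code) ? (double)code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hash_kmers(CharacterVector kmers) {
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(kmers[i]);
    int k = LENGTH(kmers[i]);
    if (k < 1 || k > 31) stop("k-mer length must be between 1 and 31");
    uint64_t code;
    out[i] = canonical_code_at(s, 0, k, code) ? (double)h1_hash(code) : NA_REAL;
  }
  return out;
}

// Windowed minhash sketches for a vector of sequences. One row per retained
// feature: seq (1-based input index), window (0-based), feature (double).
// Windowing: if L < k a single empty window [0, L); else m = (L-k)/t + 1
// windows, window i = [i*t, min(i*t + w, L)).
// [[Rcpp::export]]
DataFrame cpp_sketch_windows(CharacterVector seqs, int k, int s, int w, int t) {
  if (k < 1 || s < 1 || w < k || t < 1) stop("invalid sketch parameters");
  std::vector<int> seq_col, win_col;
  std::vector<double> feat_col;
  for (int i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* s_ptr = CHAR(seqs[i]);
    int L = LENGTH(seqs[i]);
    if (L < k) continue; // single window, no k-mers
    int m = (L - k) / t + 1;
    for (int j = 0; j < m; ++j) {
      int start = j * t;
      int end = std::min(start + w, L);
      std::vector<uint64_t> sk = sketch_span(s_ptr, start, end, k, s);
      for (uint64_t f : sk) {
        seq_col.push_back(i + 1);
        win_col.push_back(j);
        feat_col.push_back((double)f);
      }
    }
  }
  return DataFrame::create(_["seq"] = seq_col, _["window"] = win_col,
                           _["feature"] = feat_col,
                           _["stringsAsFactors"] = false);
}

// Number of windows per sequence under the same rule (1 if L < k).
// [[Rcpp::export]]
IntegerVector cpp_window_counts(IntegerVector lengths, int k, int t) {
  int n = lengths.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int L = lengths[i];
    out[i] = (L < k) ? 1 : (L - k) / t + 1;
  }
  return out;
}

// Pairwise Hamming distances between equal-length strings (row: a, col: b).
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_cross(CharacterVector a, CharacterVector b) {
  int na = a.size(), nb = b.size();
  IntegerMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    const char* ai = CHAR(a[i]);
    int la = LENGTH(a[i]);
    for (int j = 0; j < nb; ++j) {
      const char* bj = CHAR(b[j]);
      if (LENGTH(b[j]) != la)
        stop("Hamming distance requires equal-length strings");
      int d = 0;
      for (int p = 0; p < la; ++p) d += (ai[p] != bj[p]);
      out(i, j) = d;
    }
  }
  return out;
}
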