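#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit packing of DNA words: A=00, C=01, G=10, T=11.  Words containing any
// other letter (N and friends) are dropped, so they contribute nothing to any
// kernel sum.  Word length is limited to 15 so a packed code fits a signed int.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::vector<uint32_t> encode_valid_windows(const std::string& s, int l) {
  std::vector<uint32_t> out;
  int n = (int)s.size();
  if (n < l) return out;
  out.reserve(n - l + 1);
  uint32_t code = 0;
  uint32_t mask = (uint32_t(1) << (2 * l)) - 1u;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++valid >= l) out.push_back(code);
  }
  return out;
}

// Number of mismatching positions between two packed words.
static inline int word_mismatches(uint32_t a, uint32_t b) {
  uint32_t x = a ^ b;
  x = (x | (x >> 1)) & 0x55555555u;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

// w must have length l + 1 with zeros beyond the mismatch truncation point, so
// the inner loop needs no branch.
static double pair_kernel(const std::vector<uint32_t>& A,
                          const std::vector<uint32_t>& B,
                          const std::vector<double>& w) {
  double s = 0.0;
  for (size_t i = 0; i < A.size(); ++i) {
    uint32_t a = A[i];
    for (size_t j = 0; j < B.size(); ++j) {
      s += w[word_mismatches(a, B[j])];
    }
  }
  return s;
}

static std::vector<double> as_weights(NumericVector w) {
  return std::vector<double>(w.begin(), w.end());
}

// [[Rcpp::export]]
IntegerVector cpp_encode_codes(std::string seq, int l) {
  std::vector<uint32_t> v = encode_valid_windows(seq, l);
  IntegerVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (int)v[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_codes(IntegerVector codes, int l) {
  CharacterVector out(codes.size());
  const char* bases = "ACGT";
  std::string buf(l, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint32_t c = (uint32_t)codes[i];
    for (int p = l - 1; p >= 0; --p) {
      buf[p] = bases[c & 3u];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_gkm_kernel(std::string seq_a, std::string seq_b,
                      NumericVector weights, int l) {
  std::vector<uint32_t> A = encode_valid_windows(seq_a, l);
  std::vector<uint32_t> B = encode_valid_windows(seq_b, l);
  return pair_kernel(A, B, as_weights(weights));
}

// [[Rcpp::export]]
NumericMatrix cpp_gkm_gram(CharacterVector seqs, NumericVector weights, int l) {
  int n = seqs.size();
  std::vector<std::vector<uint32_t> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_valid_windows(as<std::string>(seqs[i]), l);
  std::vector<double> w = as_weights(weights);
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = pair_kernel(enc[i], enc[j], w);
      K(i, j) = v;
      K(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_gkm_cross(CharacterVector seqs_a, CharacterVector seqs_b,
                            NumericVector weights, int l) {
  int na = seqs_a.size(), nb = seqs_b.size();
  std::vector<std::vector<uint32_t> > ea(na), eb(nb);
  for (int i = 0; i < na; ++i) ea[i] = encode_valid_windows(as<std::string>(seqs_a[i]), l);
  for (int j = 0; j < nb; ++j) eb[j] = encode_valid_windows(as<std::string>(seqs_b[j]), l);
  std::vector<double> w = as_weights(weights);
  NumericMatrix K(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) K(i, j) = pair_kernel(ea[i], eb[j], w);
    Rcpp::checkUserInterrupt();
  }
  return K;
}

// [[Rcpp::export]]
NumericVector cpp_gkm_self(CharacterVector seqs, NumericVector weights, int l) {
  int n = seqs.size();
  std::vector<double> w = as_weights(weights);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uint32_t> e = encode_valid_windows(as<std::string>(seqs[i]), l);
    out[i] = pair_kernel(e, e, w);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Score a set of bare l-mers against a weighted bag of support-vector windows:
// score[q] = sum_j win_weights[j] * w(mismatches(query[q], win_codes[j])).
// [[Rcpp::export]]
NumericVector cpp_score_lmers(IntegerVector query_codes, IntegerVector win_codes,
                              NumericVector win_weights, NumericVector weights) {
  R_xlen_t nq = query_codes.size(), nw = win_codes.size();
  std::vector<double> w = as_weights(weights);
  NumericVector out(nq);
  for (R_xlen_t q = 0; q < nq; ++q) {
    uint32_t qc = (uint32_t)query_codes[q];
    double s = 0.0;
    for (R_xlen_t j = 0; j < nw; ++j) {
      s += win_weights[j] * w[word_mismatches(qc, (uint32_t)win_codes[j])];
    }
    out[q] = s;
    if ((q & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// All windows of |seq| within max_mm mismatches of pattern (exact alphabet;
// windows containing non-ACGT letters never match).  Positions are 0-based.
// [[Rcpp::export]]
DataFrame cpp_mismatch_scan(std::string seq, std::string pattern, int max_mm) {
  int l = (int)pattern.size();
  int n = (int)seq.size();
  std::vector<int> pos;
  std::vector<int> mm;
  if (n >= l) {
    for (int i = 0; i + l <= n; ++i) {
      int d = 0;
      bool ok = true;
      for (int p = 0; p < l; ++p) {
        char c = seq[i + p];
        if (base_code(c) < 0) { ok = false; break; }
        if (c != pattern[p] && ++d > max_mm) { ok = false; break; }
      }
      if (ok) { pos.push_back(i); mm.push_back(d); }
    }
  }
  return DataFrame::create(_["position"] = wrap(pos), _["mismatches"] = wrap(mm));
}
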