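#include "core.h"
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// [[Rcpp::export(name = ".encode_kmers_cpp")]]
NumericVector encode_kmers_cpp(CharacterVector seqs) {
  int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    const char* p = CHAR(STRING_ELT(seqs, s));
    i64 code = 0;
    for (int i = 0; p[i]; ++i) {
      int b = base_code(p[i]);
      if (b < 0)
        stop("non-ACGT character '%c' at position %d of k-mer %d", p[i],
             i + 1, s + 1);
      code = code * 4 + b;
      if (i >= 26) stop("k-mer longer than 26 bases is not supported");
    }
    out[s] = (double)code;
  }
  return out;
}

// [[Rcpp::export(name = ".decode_kmers_cpp")]]
CharacterVector decode_kmers_cpp(NumericVector codes, int k) {
  static const char bases[] = "ACGT";
  int n = codes.size();
  CharacterVector out(n);
  std::string buf(k, 'A');
  for (int s = 0; s < n; ++s) {
    i64 c = (i64)codes[s];
    for (int i = k - 1; i >= 0; --i) {
      buf[i] = bases[c & 3];
      c >>= 2;
    }
    out[s] = buf;
  }
  return out;
}

// Sorted k-spectrum of a genome string; windows containing non-ACGT bases
// are skipped entirely.
// [[Rcpp::export(name = ".spectrum_codes_cpp")]]
NumericVector spectrum_codes_cpp(std::string genome, int k) {
  i64 L = (i64)genome.size();
  std::vector<i64> codes;
  if (L >= k) codes.reserve(L - k + 1);
  i64 code = 0, valid = 0;  // number of trailing valid bases
  i64 mask_len = k;
  i64 mod = ((i64)1) << (2 * k);  // 4^k, k <= 26
  for (i64 i = 0; i < L; ++i) {
    int b = base_code(genome[i]);
    if (b < 0) {
      valid = 0;
      code = 0;
      continue;
    }
    code = ((code * 4) + b) % mod;
    if (++valid >= mask_len) codes.push_back(code);
  }
  std::sort(codes.begin(), codes.end());
  return NumericVector(codes.begin(), codes.end());
}

// Prefix-doubling suffix array (0-based positions), non-ACGT ranks above T.
// [[Rcpp::export(name = ".suffix_array_cpp")]]
IntegerVector suffix_array_cpp(std::string genome) {
  int L = (int)genome.size();
  if (L == 0) stop("genome must be non-empty");
  std::vector<int> sa(L), r(L), tmp(L);
  for (int i = 0; i < L; ++i) {
    int b = base_code(genome[i]);
    r[i] = b < 0 ? 4 : b;
  }
  std::iota(sa.begin(), sa.end(), 0);
  for (int h = 1;; h *= 2) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + h < L ? r[a + h] : -1;
      int rb = b + h < L ? r[b + h] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < L; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    r = tmp;
    if (r[sa[L - 1]] == L - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// K-mer codes read through the suffix array, in suffix-array order, skipping
// suffixes shorter than k and windows containing non-ACGT bases.
// [[Rcpp::export(name = ".sa_spectrum_codes_cpp")]]
NumericVector sa_spectrum_codes_cpp(std::string genome, IntegerVector sa,
                                    int k) {
  i64 L = (i64)genome.size();
  // precompute for each position the length of the valid ACGT run ahead
  std::vector<int> run(L + 1, 0);
  for (i64 i = L - 1; i >= 0; --i)
    run[i] = base_code(genome[i]) < 0 ? 0 : run[i + 1] + 1;
  std::vector<i64> codes;
  codes.reserve(sa.size());
  for (int j = 0; j < sa.size(); ++j) {
    i64 p = sa[j];
    if (L - p < k || run[p] < k) continue;
    i64 code = 0;
    for (int i = 0; i < k; ++i) code = code * 4 + base_code(genome[p + i]);
    codes.push_back(code);
  }
  return NumericVector(codes.begin(), codes.end());
}

// First-occurrence positions and multiplicities of the distinct values of a
// sorted list, used when collapsing S for segment fitting.
// [[Rcpp::export(name = ".distinct_ranks_cpp")]]
List distinct_ranks_cpp(NumericVector values) {
  i64 N = values.size();
  std::vector<double> xs;
  std::vector<double> ranks, occs;
  for (i64 i = 0; i < N; ++i) {
    if (i == 0 || values[i] != values[i - 1]) {
      xs.push_back(values[i]);
      ranks.push_back((double)i);
      occs.push_back(1);
    } else {
      occs.back() += 1;
    }
  }
  return List::create(_["x"] = NumericVector(xs.begin(), xs.end()),
                      _["rank"] = NumericVector(ranks.begin(), ranks.end()),
                      _["occ"] = NumericVector(occs.begin(), occs.end()));
}
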