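#include "core.h"
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// CHD-style minimal perfect hash: keys are thrown into ~n/3 buckets; buckets
// are processed in decreasing size, searching per bucket for the smallest
// displacement seed under which all its keys land on distinct free slots of
// [0, n).  Restricted to the key set the map is a bijection; non-keys map to
// an arbitrary slot.

static inline u64 mphf_bucket(u64 key, u64 m) { return splitmix64(key) % m; }
static inline u64 mphf_slot(u64 key, u64 seed, u64 n) {
  return splitmix64(key ^ (0xC2B2AE3D27D4EB4FULL * seed)) % n;
}

// [[Rcpp::export(name = ".mphf_build_cpp")]]
List mphf_build_cpp(NumericVector keys) {
  u64 n = keys.size();
  if (n == 0) stop("cannot build an MPHF over zero keys");
  std::vector<u64> ks(n);
  for (u64 i = 0; i < n; ++i) ks[i] = (u64)(i64)keys[i];
  {
    std::vector<u64> chk = ks;
    std::sort(chk.begin(), chk.end());
    for (u64 i = 1; i < n; ++i)
      if (chk[i] == chk[i - 1]) stop("duplicate keys are not allowed");
  }
  u64 m = (n + 2) / 3;
  if (m < 1) m = 1;
  std::vector<std::vector<u64>> buckets(m);
  for (u64 i = 0; i < n; ++i) buckets[mphf_bucket(ks[i], m)].push_back(ks[i]);
  std::vector<u64> order(m);
  std::iota(order.begin(), order.end(), 0);
  std::sort(order.begin(), order.end(), [&](u64 a, u64 b) {
    return buckets[a].size() > buckets[b].size();
  });
  std::vector<char> used(n, 0);
  std::vector<u64> seeds(m, 0);
  std::vector<u64> slots;
  for (u64 oi = 0; oi < m; ++oi) {
    u64 bidx = order[oi];
    const std::vector<u64>& bk = buckets[bidx];
    if (bk.empty()) continue;
    bool placed = false;
    for (u64 s = 1; s <= 20000000ULL; ++s) {
      slots.clear();
      bool ok = true;
      for (u64 key : bk) {
        u64 sl = mphf_slot(key, s, n);
        if (used[sl]) { ok = false; break; }
        for (u64 prev : slots)
          if (prev == sl) { ok = false; break; }
        if (!ok) break;
        slots.push_back(sl);
      }
      if (ok) {
        for (u64 sl : slots) used[sl] = 1;
        seeds[bidx] = s;
        placed = true;
        break;
      }
    }
    if (!placed) stop("MPHF displacement search failed (pathological keys)");
  }
  u64 maxseed = 0;
  for (u64 s : seeds) maxseed = std::max(maxseed, s);
  int width = bits_for(maxseed);
  BitWriter bw;
  for (u64 s : seeds) bw.append(s, width);
  List seeds_fw = List::create(_["width"] = width, _["n"] = (double)m,
                               _["bits"] = bw.to_raw(),
                               _["size_bits"] = (double)m * width);
  seeds_fw.attr("class") = "fw_seq";
  List out = List::create(
      _["n"] = (double)n, _["m"] = (double)m, _["seeds"] = seeds_fw,
      _["bits_per_key"] = (double)m * width / (double)n);
  out.attr("class") = "mphf";
  return out;
}

// [[Rcpp::export(name = ".mphf_lookup_cpp")]]
NumericVector mphf_lookup_cpp(List mphf, NumericVector keys) {
  u64 n = (u64)as<double>(mphf["n"]);
  u64 m = (u64)as<double>(mphf["m"]);
  FWView seeds;
  seeds.init(as<List>(mphf["seeds"]));
  NumericVector out(keys.size());
  for (int i = 0; i < keys.size(); ++i) {
    u64 key = (u64)(i64)keys[i];
    u64 s = seeds.get((i64)mphf_bucket(key, m));
    out[i] = (double)mphf_slot(key, s, n);
  }
  return out;
}

// exact-variant rank: one MPHF evaluation, one error-array access and a
// single probe into S
// [[Rcpp::export(name = ".exact_rank_cpp")]]
NumericVector exact_rank_cpp(List idx, List mphf, List E, List Slist,
                             NumericVector queries) {
  u64 n = (u64)as<double>(mphf["n"]);
  u64 m = (u64)as<double>(mphf["m"]);
  FWView seeds, Ev;
  seeds.init(as<List>(mphf["seeds"]));
  Ev.init(as<List>(E));
  IdxView v;
  v.init(idx);
  SView S;
  S.init(Slist);
  NumericVector out(queries.size());
  for (i64 q = 0; q < queries.size(); ++q) {
    i64 x = (i64)queries[q];
    if (x < v.X0 || x > v.Xb) {
      out[q] = -1;
      continue;
    }
    u64 key = (u64)x;
    u64 s = seeds.get((i64)mphf_bucket(key, m));
    u64 slot = mphf_slot(key, s, n);
    i64 err = unzigzag_u64(Ev.get((i64)slot));
    i64 p = (i64)std::floor(v.est(x)) - err;
    out[q] = (p >= 0 && p < S.N && S.get(p) == x) ? (double)p : -1;
  }
  return out;
}
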