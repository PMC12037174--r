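#include "core.h"
#include <algorithm>
using namespace Rcpp;

// Seeded genome generator.  The sequence is emitted in blocks of
// `repeat_unit` bases: with probability `repeat_fraction` a block is a copy
// of an earlier window (half tandem -- the immediately preceding window,
// half dispersed -- a uniformly chosen earlier position), otherwise i.i.d.
// uniform bases.  Higher repeat_fraction raises N/n of the k-spectrum, the
// quantity that drives repeat stretching.
// [[Rcpp::export(name = ".gen_genome_cpp")]]
std::string gen_genome_cpp(double length_, double repeat_fraction,
                           double repeat_unit_, double seed_) {
  static const char bases[] = "ACGT";
  i64 length = (i64)length_, unit = (i64)repeat_unit_;
  SplitMix rng((u64)(i64)seed_ * 0x9E3779B97F4A7C15ULL + 1);
  std::string g;
  g.reserve(length);
  while ((i64)g.size() < length) {
    i64 remaining = length - (i64)g.size();
    i64 blk = std::min(unit, remaining);
    if ((i64)g.size() >= unit && rng.unif() < repeat_fraction) {
      i64 src;
      if (rng.unif() < 0.5) {
        src = (i64)g.size() - unit;  // tandem copy
      } else {
        src = (i64)rng.below((u64)((i64)g.size() - unit + 1));  // dispersed
      }
      for (i64 t = 0; t < blk; ++t) g.push_back(g[src + t]);
    } else {
      for (i64 t = 0; t < blk; ++t) g.push_back(bases[rng.below(4)]);
    }
  }
  return g;
}

// Seeded sorted-list generator: n_distinct distinct codes drawn uniformly
// from [0, universe), each repeated 1 + Geometric(dup_rate) times.
// [[Rcpp::export(name = ".gen_sorted_list_cpp")]]
NumericVector gen_sorted_list_cpp(double n_distinct_, double universe_,
                                  double dup_rate, double seed_) {
  i64 nd = (i64)n_distinct_;
  i64 U = (i64)universe_;
  if (nd > U) stop("n_distinct cannot exceed the universe size");
  SplitMix rng((u64)(i64)seed_ * 0x9E3779B97F4A7C15ULL + 2);
  std::vector<i64> distinct;
  distinct.reserve(nd);
  if (nd * 3 >= U) {
    // dense regime: reservoir-style selection from the full universe
    i64 chosen = 0;
    for (i64 v = 0; v < U && chosen < nd; ++v) {
      i64 left = U - v;
      if ((i64)rng.below((u64)left) < nd - chosen) {
        distinct.push_back(v);
        ++chosen;
      }
    }
  } else {
    // sparse regime: rejection sampling
    std::vector<i64> tmp;
    while ((i64)tmp.size() < nd) {
      i64 need = nd - (i64)tmp.size();
      for (i64 t = 0; t < need; ++t) tmp.push_back((i64)rng.below((u64)U));
      std::sort(tmp.begin(), tmp.end());
      tmp.erase(std::unique(tmp.begin(), tmp.end()), tmp.end());
    }
    distinct = tmp;
  }
  std::vector<double> out;
  for (i64 v : distinct) {
    out.push_back((double)v);
    while (dup_rate > 0 && rng.unif() < dup_rate) out.push_back((double)v);
  }
  return NumericVector(out.begin(), out.end());
}
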