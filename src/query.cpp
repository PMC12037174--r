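#include "core.h"
using namespace Rcpp;

i64 search_window(const SView& S, i64 x, i64 wlo, i64 whi,
                         bool shortcut) {
  // binary search in S[wlo..whi]; with shortcut, return any hit immediately;
  // otherwise return smallest i with S[i] >= x (whi + 1 when none)
  i64 lo = wlo, hi = whi + 1;
  while (lo < hi) {
    i64 mid = (lo + hi) / 2;
    i64 v = S.get(mid);
    if (shortcut && v == x) return mid;
    if (v < x) lo = mid + 1;
    else hi = mid;
  }
  return lo;
}

// op: 0 = est, 1 = search, 2 = rank
// [[Rcpp::export(name = ".pla_query_cpp")]]
NumericVector pla_query_cpp(List idx, List Slist, NumericVector queries,
                            int op) {
  IdxView v;
  v.init(idx);
  SView S;
  if (op != 0) S.init(Slist);
  i64 n = queries.size();
  NumericVector out(n);
  for (i64 q = 0; q < n; ++q) {
    i64 x = (i64)queries[q];
    if (x < v.X0 || x > v.Xb) {
      out[q] = op == 0 ? NA_REAL : -1;
      continue;
    }
    double est = v.est(x);
    if (op == 0) {
      out[q] = est;
      continue;
    }
    i64 wlo = (i64)std::floor(est - (double)v.eps);
    i64 whi = (i64)std::ceil(est + (double)v.eps);
    if (wlo < 0) wlo = 0;
    if (whi > v.N - 1) whi = v.N - 1;
    if (op == 1 || v.variant == 1) {
      i64 p = search_window(S, x, wlo, whi, true);
      if (p > whi || S.get(p) != x) {
        out[q] = -1;
        continue;
      }
      if (op == 1) {
        out[q] = (double)p;
      } else {  // repeat-variant rank: backward scan to the first occurrence
        while (p > 0 && S.get(p - 1) == x) --p;
        out[q] = (double)p;
      }
    } else {  // basic-variant rank: find smallest i with S[i] >= x
      i64 p = search_window(S, x, wlo, whi, false);
      out[q] = (p <= whi && S.get(p) == x) ? (double)p : -1;
    }
  }
  return out;
}

// unconstrained predecessor search over X, for validating the D bracketing
// [[Rcpp::export(name = ".pla_locate_cpp")]]
NumericVector pla_locate_cpp(List idx, NumericVector queries, bool use_table) {
  IdxView v;
  v.init(idx);
  NumericVector out(queries.size());
  for (i64 q = 0; q < queries.size(); ++q) {
    i64 x = (i64)queries[q];
    if (x < v.X0 || x > v.Xb) {
      out[q] = NA_REAL;
      continue;
    }
    if (use_table) {
      out[q] = (double)v.locate(x);
    } else {
      i64 lo = 0, hi = v.b + 1;
      while (lo + 1 < hi) {
        i64 mid = (lo + hi) / 2;
        if (v.X(mid) <= x) lo = mid;
        else hi = mid;
      }
      out[q] = (double)lo;
    }
  }
  return out;
}

// prefix lookup table D: entry i is the smallest j such that the first
// prefix_bits bits of X[j] are at least i; sentinel entry = |X|
// [[Rcpp::export(name = ".prefix_table_entries_cpp")]]
NumericVector prefix_table_entries_cpp(NumericVector X, int k,
                                       int prefix_bits, double bl_) {
  i64 bl = (i64)bl_, m = X.size();
  NumericVector out(bl + 1);
  i64 j = 0;
  for (i64 i = 0; i < bl; ++i) {
    while (j < m) {
      i64 top = prefix_bits > 0 ? ((i64)X[j] >> (2 * k - prefix_bits)) : 0;
      if (top >= i) break;
      ++j;
    }
    out[i] = (double)j;
  }
  out[bl] = (double)m;
  return out;
}

// deployed-arithmetic guarantee check used by tests: max |est - rank| over
// every distinct member k-mer (basic), or max overshoot beyond the last
// occurrence (repeat); returns the two worst margins
// [[Rcpp::export(name = ".guarantee_margins_cpp")]]
NumericVector guarantee_margins_cpp(List idx, NumericVector xs,
                                    NumericVector ranks, NumericVector occs) {
  IdxView v;
  v.init(idx);
  double worst_lo = -1e300, worst_hi = -1e300;  // amounts over the bounds
  for (i64 i = 0; i < xs.size(); ++i) {
    double est = v.est((i64)xs[i]);
    double lo = ranks[i] - (double)v.eps;
    double hi = ranks[i] + (double)v.eps +
                (v.variant == 1 ? occs[i] - 1.0 : 0.0);
    if (lo - est > worst_lo) worst_lo = lo - est;
    if (est - hi > worst_hi) worst_hi = est - hi;
  }
  return NumericVector::create(worst_lo, worst_hi);
}
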