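#include "core.h"
#include <algorithm>
using namespace Rcpp;

// The streaming fitter maintains, for points (x_j, [lo_j, hi_j]) with x
// strictly increasing, the interval [A, B] of slopes m for which some line
// y = m x + c fits every range.  Eliminating the intercept c turns "a line
// fits" into the pairwise conditions
//     m >= (lo_i - hi_j) / (x_i - x_j)   and   m <= (hi_i - lo_j) / (x_i - x_j)
// for j < i (Helly's theorem in one dimension), so feasibility is exactly
// A <= B.  When a new point arrives the new pairwise bounds are tangents from
// it to two convex hulls of earlier range endpoints, found by binary search
// with exact __int128 slope comparisons.

struct Frac {  // p/q with q > 0
  i64 p, q;
};
static inline int frac_cmp(const Frac& a, const Frac& b) {
  i128 l = (i128)a.p * b.q, r = (i128)b.p * a.q;
  return l < r ? -1 : (l > r ? 1 : 0);
}

struct HPt {
  i64 x, y;
};
// compare slope(a,b) vs slope(c,d); all x strictly increasing so q > 0
static inline int slope_cmp(const HPt& a, const HPt& b, const HPt& c,
                            const HPt& d) {
  i128 l = (i128)(b.y - a.y) * (d.x - c.x);
  i128 r = (i128)(d.y - c.y) * (b.x - a.x);
  return l < r ? -1 : (l > r ? 1 : 0);
}

struct Fitter {
  std::vector<i64> xs, los, his;
  std::vector<HPt> hull_hi;  // lower convex hull of (x, hi): slopes increasing
  std::vector<HPt> hull_lo;  // upper convex hull of (x, lo): slopes decreasing
  bool bounded = false;      // A/B defined once >= 2 points
  Frac A{0, 1}, B{0, 1};

  // max slope from hull (lower hull, slopes increasing) to right point P
  static Frac tangent_max(const std::vector<HPt>& h, const HPt& P) {
    size_t lo = 0, hi = h.size() - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      // g(mid) >= g(mid+1) ?
      if (slope_cmp(h[mid], P, h[mid + 1], P) >= 0) hi = mid;
      else lo = mid + 1;
    }
    return Frac{P.y - h[lo].y, P.x - h[lo].x};
  }
  // min slope from hull (upper hull, slopes decreasing) to right point P
  static Frac tangent_min(const std::vector<HPt>& h, const HPt& P) {
    size_t lo = 0, hi = h.size() - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (slope_cmp(h[mid], P, h[mid + 1], P) <= 0) hi = mid;
      else lo = mid + 1;
    }
    return Frac{P.y - h[lo].y, P.x - h[lo].x};
  }

  // try to add a point; returns false (state unchanged) if no line fits
  bool add(i64 x, i64 lo, i64 hi) {
    if (!xs.empty() && x <= xs.back())
      stop("x-values fed to the fitter must be strictly increasing");
    if (lo > hi) stop("invalid range: lo > hi");
    Frac nA = A, nB = B;
    bool nbounded = bounded;
    if (!xs.empty()) {
      Frac cA = tangent_max(hull_hi, HPt{x, lo});
      Frac cB = tangent_min(hull_lo, HPt{x, hi});
      if (!bounded) {
        nA = cA;
        nB = cB;
      } else {
        if (frac_cmp(cA, nA) > 0) nA = cA;
        if (frac_cmp(cB, nB) < 0) nB = cB;
      }
      nbounded = true;
      if (frac_cmp(nA, nB) > 0) return false;
    }
    A = nA;
    B = nB;
    bounded = nbounded;
    xs.push_back(x);
    los.push_back(lo);
    his.push_back(hi);
    HPt ph{x, hi}, pl{x, lo};
    while (hull_hi.size() >= 2 &&
           slope_cmp(hull_hi[hull_hi.size() - 2], hull_hi.back(),
                     hull_hi.back(), ph) >= 0)
      hull_hi.pop_back();
    hull_hi.push_back(ph);
    while (hull_lo.size() >= 2 &&
           slope_cmp(hull_lo[hull_lo.size() - 2], hull_lo.back(),
                     hull_lo.back(), pl) <= 0)
      hull_lo.pop_back();
    hull_lo.push_back(pl);
    return true;
  }

  size_t n() const { return xs.size(); }

  // minimal line value at the first point, as an exact rational num/B.q:
  // with m = B (the max feasible slope) the minimal feasible intercept is
  // c = max_j (lo_j - m x_j); the value at x0 is max_j (lo_j + m (x0 - x_j)).
  i128 min_start_num() const {
    i64 x0 = xs.front();
    i128 best = (i128)los[0] * B.q;
    for (size_t j = 1; j < xs.size(); ++j) {
      i128 v = (i128)los[j] * B.q + (i128)B.p * (x0 - xs[j]);
      if (v > best) best = v;
    }
    return best;
  }
  // maximal line value at the first point (slope A, maximal intercept)
  i128 max_start_num() const {
    i64 x0 = xs.front();
    i128 best = (i128)his[0] * A.q;
    for (size_t j = 1; j < xs.size(); ++j) {
      i128 v = (i128)his[j] * A.q + (i128)A.p * (x0 - xs[j]);
      if (v < best) best = v;
    }
    return best;
  }
};

// ---------------------------------------------------------------------------
// Integer endpoint selection.  Given fitted points s..e and the breakpoint
// x-value xb at which the stored segment ends, find integer (ys, ye) such
// that the deployed interpolation est(x) between (x_s, ys) and (xb, ye)
// satisfies, at every fitted point, the floor-discretized guarantee
//     lo_j <= est(x_j) < hi_j + 1      (i.e. floor(est) in [lo_j, hi_j]).
// A first pass prefers pairs meeting the strict ranges est in [lo_j, hi_j];
// if no such lattice pair exists (common when the feasible polygon of real
// lines is thinner than one unit), the upper constraint is relaxed by the
// unit that the floor discretization absorbs.  Rounding both endpoint
// values of any feasible real line up meets the relaxed condition, so the
// relaxed pass always succeeds at full reach; 'forced' breaks therefore
// only arise from floating-point corner cases caught by re-verification.
// Within the accepted pass the feasible ys closest to the true rank curve
// is chosen, restricted to ys <= rank(x_e) - eps, which preserves the
// monotone-Ystart property while keeping stored lines centred on the data.
static bool integer_close(const std::vector<i64>& x, const std::vector<i64>& lo,
                          const std::vector<i64>& hi, size_t s, size_t e,
                          i64 xb, i64 eps, i64 ye_target, const Fitter& f,
                          i64& ys_out, i64& ye_out) {
  if (s == e) {  // degenerate: zero-slope line at the minimal feasible value
    ys_out = ye_out = lo[s];
    return true;
  }
  i64 x0 = x[s];
  i64 D = xb - x0;
  // Monotone-Ystart cap: rank(x_e) - eps = lo[e].  In the steep regime every
  // feasible start value sits below it; in the near-flat regime the explicit
  // integer line with ys exactly at the cap fits, so restricting the search
  // to ys <= cap never loses feasibility and guarantees that consecutive
  // start values are non-decreasing.
  i64 cap = lo[e];
  i64 ys_hi = std::min(hi[s], cap);
  // preferred values: track the true rank curve so the stored line (and the
  // exact variant's error entries) stay centred
  i64 ys_target = std::min(lo[s] + eps, cap);
  for (int relaxed = 0; relaxed <= 1; ++relaxed) {
    i64 best_ys = INT64_MIN, best_L = 0, best_U = 0;
    for (i64 ys = lo[s]; ys <= ys_hi; ++ys) {
      bool ok = true;
      i64 L = INT64_MIN, U = INT64_MAX;
      for (size_t j = s + 1; j <= e && ok; ++j) {
        i64 dxj = x[j] - x0;   // > 0
        i64 dbx = xb - x[j];   // >= 0
        if (dbx == 0) {
          if (lo[j] > L) L = lo[j];
          if (hi[j] < U) U = hi[j];
        } else {
          i64 Lj = ceildiv_i128((i128)lo[j] * D - (i128)ys * dbx, dxj);
          // strict: est <= hi_j ; relaxed: est < hi_j + 1 (exact integers)
          i64 Uj = relaxed
            ? floordiv_i128((i128)(hi[j] + 1) * D - 1 - (i128)ys * dbx, dxj)
            : floordiv_i128((i128)hi[j] * D - (i128)ys * dbx, dxj);
          if (Lj > L) L = Lj;
          if (Uj < U) U = Uj;
        }
        if (L > U) ok = false;
      }
      if (ok && L <= U) {
        i64 d_new = ys > ys_target ? ys - ys_target : ys_target - ys;
        i64 d_old = best_ys > ys_target ? best_ys - ys_target
                                        : ys_target - best_ys;
        if (best_ys == INT64_MIN || d_new < d_old) {
          best_ys = ys;
          best_L = L;
          best_U = U;
        }
        if (ys >= ys_target) break;  // candidates only get farther now
      }
    }
    if (best_ys != INT64_MIN) {
      i64 ye = ye_target;
      if (ye < best_L) ye = best_L;
      if (ye > best_U) ye = best_U;
      ys_out = best_ys;
      ye_out = ye;
      return true;
    }
  }
  return false;
}

// verify with deployed (double) query arithmetic against the discretized
// guarantee; returns first violating point index, or -1 when none
static i64 verify_segment(const std::vector<i64>& x, const std::vector<i64>& lo,
                          const std::vector<i64>& hi, size_t s, size_t e,
                          i64 xb, i64 ys, i64 ye, i64 N) {
  i64 x0 = x[s];
  for (size_t j = s; j <= e; ++j) {
    double est = plaest_segment(x[j], x0, xb, ys, ye, N);
    if (est < (double)lo[j] || est >= (double)hi[j] + 1.0) return (i64)j;
  }
  return -1;
}

struct SegResult {
  std::vector<i64> X, Ys, Ye;
  i64 forced = 0;
};

// core construction: distinct x-values with their first-occurrence ranks and
// multiplicities; variant 0 = basic, 1 = repeat-stretched
static SegResult build_segments_core(const std::vector<i64>& x,
                                     const std::vector<i64>& rank,
                                     const std::vector<i64>& occ, i64 eps,
                                     int variant, i64 N) {
  size_t nd = x.size();
  SegResult res;
  std::vector<i64> lo(nd), hi(nd);
  for (size_t i = 0; i < nd; ++i) {
    lo[i] = rank[i] - eps;
    hi[i] = rank[i] + eps + (variant == 1 ? occ[i] - 1 : 0);
  }
  if (nd == 1) {
    res.X = {x[0]};
    res.Ys = {rank[0]};
    res.Ye = {rank[0]};
    return res;
  }
  res.X.push_back(x[0]);
  res.Ye.push_back(0);  // placeholder, patched to Ystart[0] at the end
  size_t s = 0;
  for (;;) {
    if (s == nd - 1) {
      // lone trailing point: it is the terminal breakpoint pushed by the
      // previous (repeat-variant) close; only its exact start value is needed
      res.Ys.push_back(rank[s]);
      break;
    }
    Fitter f;
    size_t e = s;
    f.add(x[s], lo[s], hi[s]);
    while (e + 1 < nd && f.add(x[e + 1], lo[e + 1], hi[e + 1])) ++e;
    bool truncated = false;
    i64 ys = 0, ye = 0;
    Fitter refit;           // used only after truncation
    const Fitter* fit = &f;
    for (;;) {
      bool is_final = (e == nd - 1);
      size_t xb_idx = (variant == 1 && !is_final) ? e + 1 : e;
      i64 xb = x[xb_idx];
      i64 ye_target = (xb_idx < nd) ? rank[xb_idx]
                                    : rank[e];  // rank at the breakpoint
      if (integer_close(x, lo, hi, s, e, xb, eps, ye_target, *fit, ys, ye)) {
        i64 v = verify_segment(x, lo, hi, s, e, xb, ys, ye, N);
        if (v < 0) break;  // segment holds under deployed arithmetic
        e = ((size_t)v > s) ? (size_t)v - 1 : s;
      } else {
        e = (e > s) ? e - 1 : s;
      }
      truncated = true;
      refit = Fitter();
      for (size_t j = s; j <= e; ++j) refit.add(x[j], lo[j], hi[j]);
      fit = &refit;
    }
    if (truncated) ++res.forced;
    bool is_final = (e == nd - 1);
    size_t xb_idx = (variant == 1 && !is_final) ? e + 1 : e;
    res.Ys.push_back(ys);
    res.X.push_back(x[xb_idx]);
    res.Ye.push_back(ye);
    if (is_final) {
      {
        // terminal breakpoint needs a start value for queries hitting X[b]
        // exactly; the true rank is exact and keeps Ystart monotone
        res.Ys.push_back(rank[e]);
      }
      break;
    }
    s = (variant == 1) ? xb_idx : e;
  }
  res.Ye[0] = res.Ys[0];
  return res;
}

// ------------------------------- R interface -------------------------------

// [[Rcpp::export(name = ".fitter_new_cpp")]]
SEXP fitter_new_cpp() {
  Rcpp::XPtr<Fitter> p(new Fitter(), true);
  return p;
}

// [[Rcpp::export(name = ".fitter_add_cpp")]]
bool fitter_add_cpp(SEXP fp, double x, double lo, double hi) {
  Rcpp::XPtr<Fitter> p(fp);
  return p->add((i64)x, (i64)lo, (i64)hi);
}

// [[Rcpp::export(name = ".fitter_size_cpp")]]
double fitter_size_cpp(SEXP fp) {
  Rcpp::XPtr<Fitter> p(fp);
  return (double)p->n();
}

// extract the minimal-start feasible line: real values at first/last point
// [[Rcpp::export(name = ".fitter_extract_cpp")]]
List fitter_extract_cpp(SEXP fp) {
  Rcpp::XPtr<Fitter> p(fp);
  if (p->n() == 0) stop("fitter is empty: nothing to extract");
  if (p->n() == 1) {
    double y = (double)p->los[0];
    return List::create(_["x_first"] = (double)p->xs[0],
                        _["x_last"] = (double)p->xs[0], _["y_first"] = y,
                        _["y_last"] = y);
  }
  i128 num = p->min_start_num();
  double yf = (double)((long double)num / (long double)p->B.q);
  i64 x0 = p->xs.front(), x1 = p->xs.back();
  i128 numl = num + (i128)p->B.p * (x1 - x0);
  double yl = (double)((long double)numl / (long double)p->B.q);
  return List::create(_["x_first"] = (double)x0, _["x_last"] = (double)x1,
                      _["y_first"] = yf, _["y_last"] = yl);
}

static void as_i64(const NumericVector& v, std::vector<i64>& out) {
  out.resize(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (i64)v[i];
}

// [[Rcpp::export(name = ".build_segments_cpp")]]
List build_segments_cpp(NumericVector x, NumericVector rank, NumericVector occ,
                        double eps, int variant, double N) {
  std::vector<i64> xi, ri, oi;
  as_i64(x, xi);
  as_i64(rank, ri);
  as_i64(occ, oi);
  SegResult r = build_segments_core(xi, ri, oi, (i64)eps, variant, (i64)N);
  return List::create(
      _["X"] = NumericVector(r.X.begin(), r.X.end()),
      _["Ystart"] = NumericVector(r.Ys.begin(), r.Ys.end()),
      _["Yend"] = NumericVector(r.Ye.begin(), r.Ye.end()),
      _["forced"] = (double)r.forced);
}

// Exact minimum piece count over break positions (test oracle): pairwise
// (Helly) feasibility computed incrementally -- an algorithm and code path
// independent of the hull-based streaming fitter.
// mode 0: shared breakpoints (adjacent pieces share their boundary point,
//         basic-variant semantics); mode 1: partition with a free trailing
//         point (repeat-variant semantics, where a lone final k-mer becomes
//         the terminal breakpoint of the previous piece).
// [[Rcpp::export(name = ".min_segments_oracle_cpp")]]
double min_segments_oracle_cpp(NumericVector x, NumericVector lo,
                               NumericVector hi, int mode) {
  std::vector<i64> xi, loi, hii;
  as_i64(x, xi);
  as_i64(lo, loi);
  as_i64(hi, hii);
  size_t nd = xi.size();
  if (nd <= 1) return 0;
  std::vector<size_t> reach(nd);
  for (size_t j = 0; j < nd; ++j) {
    Frac A{0, 1}, B{0, 1};
    bool bounded = false, broke = false;
    size_t i = j + 1;
    for (; i < nd; ++i) {
      Frac nA = A, nB = B;
      bool nb = bounded;
      for (size_t t = j; t < i; ++t) {
        i64 dx = xi[i] - xi[t];
        Frac cA{loi[i] - hii[t], dx};
        Frac cB{hii[i] - loi[t], dx};
        if (!nb) {
          nA = cA;
          nB = cB;
          nb = true;
        } else {
          if (frac_cmp(cA, nA) > 0) nA = cA;
          if (frac_cmp(cB, nB) < 0) nB = cB;
        }
      }
      if (nb && frac_cmp(nA, nB) > 0) {
        broke = true;
        break;
      }
      A = nA;
      B = nB;
      bounded = nb;
    }
    reach[j] = broke ? i - 1 : nd - 1;
  }
  const i64 INF = ((i64)1) << 60;
  if (mode == 0) {
    std::vector<i64> dp(nd, INF);
    dp[nd - 1] = 0;
    for (size_t j = nd - 1; j-- > 0;) {
      for (size_t e = j + 1; e <= reach[j]; ++e)
        if (dp[e] + 1 < dp[j]) dp[j] = dp[e] + 1;
    }
    return (double)dp[0];
  }
  std::vector<i64> dp(nd + 1, INF);
  dp[nd] = 0;
  dp[nd - 1] = 0;  // a lone trailing point folds into the previous breakpoint
  for (size_t j = nd - 1; j-- > 0;) {
    for (size_t e = j; e <= reach[j]; ++e)
      if (dp[e + 1] + 1 < dp[j]) dp[j] = dp[e + 1] + 1;
  }
  return (double)dp[0];
}

// Exhaustive epsilon-guarantee scan over every ACGT genome of length 2..maxlen
// at word size k: builds both index variants for each spectrum and checks the
// deployed-arithmetic guarantee and the structural invariants for every
// member k-mer.  Returns counters (all violation counts must be zero).
// [[Rcpp::export(name = ".eps_guarantee_scan_cpp")]]
List eps_guarantee_scan_cpp(int maxlen, int k, double eps_) {
  i64 eps = (i64)eps_;
  i64 genomes = 0, eps_viol = 0, mono_viol = 0, bound_viol = 0, brep_viol = 0;
  std::vector<int> g;
  std::vector<i64> codes, dx, dr, doc, lo, hi;
  for (int L = k; L <= maxlen; ++L) {
    g.assign(L, 0);
    for (;;) {
      ++genomes;
      // spectrum
      codes.clear();
      for (int i = 0; i + k <= L; ++i) {
        i64 c = 0;
        for (int t = 0; t < k; ++t) c = c * 4 + g[i + t];
        codes.push_back(c);
      }
      std::sort(codes.begin(), codes.end());
      i64 N = (i64)codes.size();
      dx.clear();
      dr.clear();
      doc.clear();
      for (i64 i = 0; i < N; ++i) {
        if (i == 0 || codes[i] != codes[i - 1]) {
          dx.push_back(codes[i]);
          dr.push_back(i);
          doc.push_back(1);
        } else {
          doc.back()++;
        }
      }
      i64 b_basic = 0, b_rep = 0;
      for (int variant = 0; variant <= 1; ++variant) {
        SegResult r = build_segments_core(dx, dr, doc, eps, variant, N);
        i64 b = (i64)r.X.size() - 1;
        if (variant == 0) b_basic = b; else b_rep = b;
        for (size_t i = 0; i + 1 < r.Ys.size(); ++i)
          if (r.Ys[i] > r.Ys[i + 1]) ++mono_viol;
        if (variant == 0)
          for (size_t i = 0; i < r.Ye.size(); ++i) {
            i64 d = r.Ye[i] - r.Ys[i];
            if (d > 2 * eps || d < -2 * eps) ++bound_viol;
          }
        // guarantee for every distinct member k-mer
        size_t seg = 0;
        for (size_t i = 0; i < dx.size(); ++i) {
          while (seg + 1 < r.X.size() && r.X[seg + 1] <= dx[i]) ++seg;
          double est;
          if (seg + 1 >= r.X.size() || dx[i] == r.X[r.X.size() - 1]) {
            est = (double)r.Ys[r.X.size() - 1];
          } else {
            est = plaest_segment(dx[i], r.X[seg], r.X[seg + 1], r.Ys[seg],
                                 r.Ye[seg + 1], N);
          }
          double lo_b = (double)(dr[i] - eps);
          double hi_b =
              (double)(dr[i] + eps + (variant == 1 ? doc[i] - 1 : 0));
          if (est < lo_b || est >= hi_b + 1.0) ++eps_viol;
        }
      }
      if (b_rep > b_basic) ++brep_viol;
      // odometer
      int pos = L - 1;
      while (pos >= 0 && g[pos] == 3) g[pos--] = 0;
      if (pos < 0) break;
      ++g[pos];
    }
  }
  return List::create(_["genomes"] = (double)genomes,
                      _["eps_violations"] = (double)eps_viol,
                      _["monotone_violations"] = (double)mono_viol,
                      _["endpoint_bound_violations"] = (double)bound_viol,
                      _["repeat_segment_violations"] = (double)brep_viol);
}
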