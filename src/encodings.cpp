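#include "core.h"
using namespace Rcpp;

// ---------------- Elias-Fano ----------------
// Monotone values from universe U, shifted by `offset` so negatives (e.g.
// Ystart values as low as -eps) can be stored.  Low-bit width
// l = floor(lg(U/m)) keeps the payload under m lg(U/m) + 2m + O(1) bits.

// [[Rcpp::export(name = ".ef_encode_cpp")]]
List ef_encode_cpp(NumericVector values, double U_, double offset_) {
  i64 m = values.size(), U = (i64)U_, offset = (i64)offset_;
  if (m == 0) stop("cannot Elias-Fano encode an empty sequence");
  if (U < 1) stop("universe size must be positive");
  i64 prev = -1;
  for (i64 i = 0; i < m; ++i) {
    i64 v = (i64)values[i] - offset;
    if (v < prev) stop("values must be non-decreasing (violated at index %d)",
                       (int)i + 1);
    if (v < 0 || v >= U)
      stop("value at index %d outside universe [0, %g)", (int)i + 1, U_);
    prev = v;
  }
  int l = 0;
  while ((((u64)m) << (l + 1)) <= (u64)U) ++l;  // floor(lg(U/m))
  BitWriter low, high;
  std::vector<double> sel;
  i64 nones = 0;
  for (i64 i = 0; i < m; ++i) {
    i64 v = (i64)values[i] - offset;
    low.append((u64)v & ((l == 64) ? ~0ULL : (((u64)1 << l) - 1)), l);
    u64 pos = (u64)(v >> l) + i;
    high.set_bit(pos);
    if (nones % 256 == 0) sel.push_back((double)pos);
    ++nones;
  }
  // high bit-vector length m + (U >> l) + 1; pad with zero words
  u64 hbits = (u64)m + ((u64)U >> l) + 1;
  u64 need_words = (hbits + 63) / 64 + 1;
  if (high.w.size() < need_words) high.w.resize(need_words, 0);
  high.nbits = hbits;
  double size_bits = (double)m * l + (double)hbits;
  double overhead_bits = (double)sel.size() * 64.0;
  List out = List::create(
      _["m"] = (double)m, _["U"] = U_, _["l"] = l, _["offset"] = offset_,
      _["low"] = low.to_raw(), _["high"] = high.to_raw(),
      _["sel"] = NumericVector(sel.begin(), sel.end()),
      _["size_bits"] = size_bits, _["overhead_bits"] = overhead_bits);
  out.attr("class") = "ef_seq";
  return out;
}

// [[Rcpp::export(name = ".ef_access_cpp")]]
NumericVector ef_access_cpp(List seq, NumericVector idx) {
  EFView v;
  v.init(seq);
  NumericVector out(idx.size());
  for (int t = 0; t < idx.size(); ++t) {
    i64 i = (i64)idx[t];
    if (i < 0 || i >= v.m) stop("index out of range");
    out[t] = (double)v.get(i);
  }
  return out;
}

// ---------------- fixed width ----------------

// [[Rcpp::export(name = ".fw_encode_cpp")]]
List fw_encode_cpp(NumericVector values, int width) {
  i64 n = values.size();
  if (width < 1 || width > 56) stop("width must be in 1..56");
  BitWriter bw;
  for (i64 i = 0; i < n; ++i) {
    double d = values[i];
    if (d < 0) stop("fixed-width values must be non-negative");
    u64 v = (u64)d;
    if (width < 64 && v >= ((u64)1 << width))
      stop("value %g does not fit in %d bits", d, width);
    bw.append(v, width);
  }
  List out = List::create(_["width"] = width, _["n"] = (double)n,
                          _["bits"] = bw.to_raw(),
                          _["size_bits"] = (double)n * width);
  out.attr("class") = "fw_seq";
  return out;
}

// [[Rcpp::export(name = ".fw_access_cpp")]]
NumericVector fw_access_cpp(List seq, NumericVector idx) {
  FWView v;
  v.init(seq);
  NumericVector out(idx.size());
  for (int t = 0; t < idx.size(); ++t) {
    i64 i = (i64)idx[t];
    if (i < 0 || i >= v.n) stop("index out of range");
    out[t] = (double)v.get(i);
  }
  return out;
}

// ---------------- delta-from-uniform X encoding ----------------
// Stores X[i] - floor(i * U / m) (bias-shifted to be non-negative) at
// constant width; reconstruction is exact.

// [[Rcpp::export(name = ".dxu_encode_cpp")]]
List dxu_encode_cpp(NumericVector X, int k) {
  i64 m = X.size();
  if (m == 0) stop("cannot encode an empty breakpoint array");
  i64 U = ((i64)1) << (2 * k);
  i64 dmin = 0, dmax = 0;
  std::vector<i64> d(m);
  i64 prev = -1;
  for (i64 i = 0; i < m; ++i) {
    i64 x = (i64)X[i];
    if (x <= prev) stop("breakpoints must be strictly increasing");
    if (x < 0 || x >= U) stop("breakpoint outside k-mer universe");
    prev = x;
    d[i] = x - floordiv_i128((i128)i * U, m);
    if (i == 0 || d[i] < dmin) dmin = d[i];
    if (i == 0 || d[i] > dmax) dmax = d[i];
  }
  int width = bits_for((u64)(dmax - dmin));
  BitWriter bw;
  for (i64 i = 0; i < m; ++i) bw.append((u64)(d[i] - dmin), width);
  List deltas = List::create(_["width"] = width, _["n"] = (double)m,
                             _["bits"] = bw.to_raw(),
                             _["size_bits"] = (double)m * width);
  deltas.attr("class") = "fw_seq";
  List out = List::create(_["width"] = width, _["bias"] = (double)dmin,
                          _["m"] = (double)m, _["U"] = (double)U,
                          _["k"] = k, _["deltas"] = deltas,
                          _["size_bits"] = (double)m * width);
  out.attr("class") = "dxu_seq";
  return out;
}

// [[Rcpp::export(name = ".dxu_access_cpp")]]
NumericVector dxu_access_cpp(List seq, NumericVector idx) {
  DXUView v;
  v.init(seq);
  NumericVector out(idx.size());
  for (int t = 0; t < idx.size(); ++t) {
    i64 i = (i64)idx[t];
    if (i < 0 || i >= v.m) stop("index out of range");
    out[t] = (double)v.get(i);
  }
  return out;
}

// ---------------- directly addressable codes ----------------
// Layered chunks of `width` payload bits with continuation bitvectors and
// per-word rank samples for random access.

// [[Rcpp::export(name = ".dac_encode_cpp")]]
List dac_encode_cpp(NumericVector values, int width) {
  i64 n = values.size();
  if (width < 1 || width > 32) stop("chunk width must be in 1..32");
  std::vector<u64> cur(n);
  for (i64 i = 0; i < n; ++i) {
    if (values[i] < 0)
      stop("DAC values must be non-negative (zigzag-transform first)");
    cur[i] = (u64)values[i];
  }
  List layers;
  double size_bits = 0, overhead_bits = 0;
  while (!cur.empty()) {
    BitWriter chunks, cont;
    std::vector<u64> nxt;
    std::vector<double> rank;
    i64 nset = 0;
    for (size_t i = 0; i < cur.size(); ++i) {
      if (i % 64 == 0) rank.push_back((double)nset);
      chunks.append(cur[i] & (((u64)1 << width) - 1), width);
      u64 rest = cur[i] >> width;
      if (rest > 0) {
        cont.set_bit(i);
        nxt.push_back(rest);
        ++nset;
      }
    }
    // make sure the continuation vector covers all entries
    u64 cwords = (cur.size() + 63) / 64;
    if (cont.w.size() < cwords) cont.w.resize(cwords, 0);
    cont.nbits = cur.size();
    layers.push_back(List::create(
        _["chunks"] = chunks.to_raw(), _["cont"] = cont.to_raw(),
        _["rank"] = NumericVector(rank.begin(), rank.end()),
        _["n"] = (double)cur.size()));
    size_bits += (double)cur.size() * (width + 1);
    overhead_bits += (double)rank.size() * 64.0;
    cur.swap(nxt);
  }
  List out = List::create(_["width"] = width, _["n"] = (double)n,
                          _["layers"] = layers, _["size_bits"] = size_bits,
                          _["overhead_bits"] = overhead_bits);
  out.attr("class") = "dac_seq";
  return out;
}

// [[Rcpp::export(name = ".dac_access_cpp")]]
NumericVector dac_access_cpp(List seq, NumericVector idx) {
  DACView v;
  v.init(seq);
  double n = as<double>(seq["n"]);
  NumericVector out(idx.size());
  for (int t = 0; t < idx.size(); ++t) {
    i64 i = (i64)idx[t];
    if (i < 0 || i >= (i64)n) stop("index out of range");
    out[t] = (double)v.get(i);
  }
  return out;
}
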