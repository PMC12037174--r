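#ifndef PLAINDEX_CORE_H
#define PLAINDEX_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

typedef __int128 i128;
typedef int64_t i64;
typedef uint64_t u64;

// ---- exact integer division helpers (d > 0) ----
static inline i64 floordiv_i128(i128 n, i128 d) {
  i128 q = n / d;
  if ((n % d) != 0 && (n < 0)) --q;
  return (i64)q;
}
static inline i64 ceildiv_i128(i128 n, i128 d) { return -floordiv_i128(-n, d); }
// round to nearest, ties away from -inf
static inline i64 rounddiv_i128(i128 n, i128 d) {
  return floordiv_i128(2 * n + d, 2 * d);
}

// ---- base coding: A=0 C=1 G=2 T=3, anything else invalid (rank 4 in SA) ----
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Query-time interpolation along one segment, shared verbatim by
// construction-time re-verification, the exhaustive guarantee scan and the
// query path: integer differences first, then floating multiply/divide,
// clamped to [0, N-1].
static inline double plaest_segment(i64 x, i64 x0, i64 x1, i64 ys, i64 ye,
                                    i64 N) {
  double est;
  if (x1 == x0) {
    est = (double)ys;
  } else {
    est = (double)ys +
          (double)(ye - ys) * (double)(x - x0) / (double)(x1 - x0);
  }
  if (est < 0) est = 0;
  double hi = (double)(N - 1);
  if (est > hi) est = hi;
  return est;
}

// ---- bit packing ----
struct BitWriter {
  std::vector<u64> w;
  u64 nbits = 0;
  void append(u64 v, int bits) {
    if (bits == 0) return;
    u64 word = nbits >> 6, off = nbits & 63;
    if (word + 2 > w.size()) w.resize(word + 2, 0);
    w[word] |= v << off;
    if (off + bits > 64) w[word + 1] |= v >> (64 - off);
    nbits += bits;
  }
  void set_bit(u64 pos) {
    u64 word = pos >> 6;
    if (word >= w.size()) w.resize(word + 1, 0);
    w[word] |= (u64)1 << (pos & 63);
    if (pos >= nbits) nbits = pos + 1;
  }
  Rcpp::RawVector to_raw() const {
    Rcpp::RawVector r(w.size() * 8);
    if (!w.empty()) std::memcpy(RAW(r), w.data(), w.size() * 8);
    return r;
  }
};

struct BitView {
  std::vector<u64> buf;  // owned copy (RawVector need not be aligned)
  const u64* w = nullptr;
  u64 nwords = 0;
  BitView() {}
  explicit BitView(const Rcpp::RawVector& r) { attach(r); }
  void attach(const Rcpp::RawVector& r) {
    nwords = (r.size() + 7) / 8;
    buf.assign(nwords, 0);
    if (r.size() > 0) std::memcpy(buf.data(), RAW(r), r.size());
    w = buf.data();
  }
  u64 read(u64 pos, int bits) const {
    if (bits == 0) return 0;
    u64 word = pos >> 6, off = pos & 63;
    u64 v = w[word] >> off;
    if (off + bits > 64 && word + 1 < nwords) v |= w[word + 1] << (64 - off);
    if (bits < 64) v &= ((u64)1 << bits) - 1;
    return v;
  }
  bool bit(u64 pos) const { return (w[pos >> 6] >> (pos & 63)) & 1; }
};

static inline int bits_for(u64 maxval) {  // width needed to store maxval
  int b = 0;
  while (maxval > 0) { ++b; maxval >>= 1; }
  return b == 0 ? 1 : b;
}

// ---- decoded-sequence views used by the batch query path ----
// Elias-Fano view: monotone values, value(i) = (select1(i) - i) << l | low(i)
struct EFView {
  i64 m = 0;
  int l = 0;
  BitView low, high;
  std::vector<i64> sel;  // bit position of every 256th one
  i64 offset = 0;        // signed shift applied before encoding
  void init(const Rcpp::List& s) {
    m = (i64)Rcpp::as<double>(s["m"]);
    l = Rcpp::as<int>(s["l"]);
    low.attach(Rcpp::as<Rcpp::RawVector>(s["low"]));
    high.attach(Rcpp::as<Rcpp::RawVector>(s["high"]));
    Rcpp::NumericVector sv = s["sel"];
    sel.assign(sv.begin(), sv.end());
    offset = (i64)Rcpp::as<double>(s["offset"]);
  }
  i64 get(i64 i) const {
    // find the (i+1)-th set bit starting from the sampled position
    i64 block = i >> 8;
    i64 pos = block < (i64)sel.size() ? sel[block] : 0;
    i64 need = i - (block << 8);  // zero-based within block
    u64 word = pos >> 6;
    u64 cur = high.w[word] & ~(((u64)1 << (pos & 63)) - 1);
    i64 seen = 0;
    for (;;) {
      int pc = __builtin_popcountll(cur);
      if (seen + pc > need) {
        // isolate the (need - seen + 1)-th set bit in cur
        for (i64 t = need - seen; t > 0; --t) cur &= cur - 1;
        u64 bitpos = (word << 6) + __builtin_ctzll(cur);
        i64 hi = (i64)bitpos - i;
        return ((hi << l) | (i64)low.read((u64)i * l, l)) + offset;
      }
      seen += pc;
      ++word;
      cur = high.w[word];
    }
  }
};

// fixed-width view
struct FWView {
  int width = 0;
  i64 n = 0;
  BitView bits;
  void init(const Rcpp::List& s) {
    width = Rcpp::as<int>(s["width"]);
    n = (i64)Rcpp::as<double>(s["n"]);
    bits.attach(Rcpp::as<Rcpp::RawVector>(s["bits"]));
  }
  u64 get(i64 i) const { return bits.read((u64)i * width, width); }
};

// delta-from-uniform X view
struct DXUView {
  int width = 0;
  i64 bias = 0, m = 0;
  i64 U = 0;  // universe 4^k
  FWView deltas;
  void init(const Rcpp::List& s) {
    width = Rcpp::as<int>(s["width"]);
    bias = (i64)Rcpp::as<double>(s["bias"]);
    m = (i64)Rcpp::as<double>(s["m"]);
    U = (i64)Rcpp::as<double>(s["U"]);
    deltas.init(Rcpp::as<Rcpp::List>(s["deltas"]));
  }
  i64 get(i64 i) const {
    i64 uniform = floordiv_i128((i128)i * U, m);
    return (i64)deltas.get(i) + bias + uniform;
  }
};

// DAC view: layered 'payload' chunks with continuation bits + rank samples
struct DACLayerView {
  BitView chunks, cont;
  std::vector<i64> rank;  // set bits in cont before each 64-bit word
  i64 n = 0;
};
struct DACView {
  int width = 4;
  std::vector<DACLayerView> layers;
  void init(const Rcpp::List& s) {
    width = Rcpp::as<int>(s["width"]);
    Rcpp::List ls = s["layers"];
    layers.resize(ls.size());
    for (int i = 0; i < ls.size(); ++i) {
      Rcpp::List L = ls[i];
      layers[i].chunks.attach(Rcpp::as<Rcpp::RawVector>(L["chunks"]));
      layers[i].cont.attach(Rcpp::as<Rcpp::RawVector>(L["cont"]));
      Rcpp::NumericVector rv = L["rank"];
      layers[i].rank.assign(rv.begin(), rv.end());
      layers[i].n = (i64)Rcpp::as<double>(L["n"]);
    }
  }
  u64 get(i64 i) const {
    u64 v = 0;
    int shift = 0;
    i64 pos = i;
    for (size_t l = 0; l < layers.size(); ++l) {
      const DACLayerView& L = layers[l];
      v |= L.chunks.read((u64)pos * width, width) << shift;
      if (!L.cont.bit(pos)) break;
      // rank of set bits strictly before pos
      i64 word = pos >> 6;
      u64 mask = (((u64)1 << (pos & 63)) - 1);
      pos = L.rank[word] + __builtin_popcountll(L.cont.w[word] & mask);
      shift += width;
    }
    return v;
  }
};

// signed -> non-negative transform 2|d| + t, t = 1 iff d > 0
static inline u64 zigzag_u64(i64 d) {
  return d > 0 ? 2 * (u64)d + 1 : 2 * (u64)(-d);
}
static inline i64 unzigzag_u64(u64 z) {
  return (z & 1) ? (i64)(z >> 1) : -(i64)(z >> 1);
}

// view of the sorted list S: either a direct value array or an indirect view
// through filtered suffix-array positions into a genome string
struct SView {
  bool direct = true;
  Rcpp::NumericVector vals;
  std::string genome;
  Rcpp::IntegerVector pos;
  int k = 0;
  i64 N = 0;
  void init(const Rcpp::List& S) {
    direct = Rcpp::as<std::string>(S["representation"]) == "direct";
    if (direct) {
      vals = Rcpp::as<Rcpp::NumericVector>(S["values"]);
      N = vals.size();
    } else {
      genome = Rcpp::as<std::string>(S["genome"]);
      pos = Rcpp::as<Rcpp::IntegerVector>(S["pos"]);
      k = Rcpp::as<int>(S["k"]);
      N = pos.size();
    }
  }
  i64 get(i64 i) const {
    if (direct) return (i64)vals[i];
    i64 p = pos[i], c = 0;
    for (int t = 0; t < k; ++t) c = c * 4 + base_code(genome[p + t]);
    return c;
  }
};

// decoded-on-access view of a built index
struct IdxView {
  int k = 0, variant = 0;  // 0 basic, 1 repeat
  i64 eps = 0, N = 0, b = 0;
  bool x_delta = true;
  DXUView Xd;
  EFView Xef, Ys;
  FWView Yend_fw;    // basic: zigzag delta vs Ystart
  DACView Yend_dac;  // repeat
  FWView D;
  int prefix_bits = 0;
  i64 bl = 0;
  i64 X0 = 0, Xb = 0;
  void init(const Rcpp::List& idx) {
    using Rcpp::as;
    using Rcpp::List;
    k = as<int>(idx["k"]);
    eps = (i64)as<double>(idx["eps"]);
    N = (i64)as<double>(idx["N"]);
    b = (i64)as<double>(idx["b"]);
    variant = as<std::string>(idx["variant"]) == "repeat" ? 1 : 0;
    x_delta = as<std::string>(idx["x_encoding"]) == "delta";
    if (x_delta) Xd.init(as<List>(idx["X_enc"]));
    else Xef.init(as<List>(idx["X_enc"]));
    Ys.init(as<List>(idx["Ystart_enc"]));
    if (variant == 0) Yend_fw.init(as<List>(idx["Yend_enc"]));
    else Yend_dac.init(as<List>(idx["Yend_enc"]));
    List Dt = idx["D"];
    D.init(as<List>(Dt["entries"]));
    prefix_bits = as<int>(Dt["prefix_bits"]);
    bl = (i64)as<double>(Dt["bl"]);
    X0 = (i64)as<double>(idx["X0"]);
    Xb = (i64)as<double>(idx["Xb"]);
  }
  i64 X(i64 i) const { return x_delta ? Xd.get(i) : Xef.get(i); }
  i64 Ystart(i64 i) const { return Ys.get(i); }
  i64 Yend(i64 i) const {
    u64 z = variant == 0 ? Yend_fw.get(i) : Yend_dac.get(i);
    return Ystart(i) + unzigzag_u64(z);
  }
  // largest i with X[i] <= x, bracketed by the prefix table
  i64 locate(i64 x) const {
    i64 y = prefix_bits > 0 ? (x >> (2 * k - prefix_bits)) : 0;
    i64 lo = (i64)D.get(y) - 1;
    if (lo < 0) lo = 0;
    i64 hi = (i64)D.get(y + 1);  // exclusive
    if (hi > b + 1) hi = b + 1;
    while (lo + 1 < hi) {
      i64 mid = (lo + hi) / 2;
      if (X(mid) <= x) lo = mid;
      else hi = mid;
    }
    return lo;
  }
  double est(i64 x) const {
    i64 i = locate(x);
    if (i >= b) return (double)Ystart(b);
    return plaest_segment(x, X(i), X(i + 1), Ystart(i), Yend(i + 1), N);
  }
};

// splitmix64: the package's named, explicitly-seeded PRNG
static inline u64 splitmix64(u64 x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
struct SplitMix {
  u64 s;
  explicit SplitMix(u64 seed) : s(seed) {}
  u64 next() { s += 0x9E3779B97F4A7C15ULL;
    u64 x = s;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  u64 below(u64 n) { return next() % n; }
};

#endif
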