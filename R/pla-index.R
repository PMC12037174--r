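#' Prefix lookup table over breakpoint k-mers
#'
#' Brackets the binary search over the breakpoint array X: entry i of D is
#' the smallest position j such that the top `lg(b*ell)` bits of `X[j]` are
#' at least i, with a sentinel entry `|X|` appended.  The load factor is set
#' to `ell = 2^floor(lg b) / (16 b)` so that `b*ell` is a power of two of
#' about b/16 (clamped to at least 1); a query then binary-searches X only
#' between `D[y]-1` and `D[y+1]`, where y is the top bits of the query.
#'
#' @param X strictly increasing breakpoint codes (length b+1).
#' @param k k-mer length.
#' @param bl optional override of the table size `b*ell` (a power of two);
#'   by default derived from b as above.
#' @return a `prefix_table` with fields `ell`, `bl`, `prefix_bits`,
#'   `entries` (fixed-width packed), `size_bits`.
#' @export
build_prefix_table <- function(X, k, bl = NULL) {
  b <- length(X) - 1L
  if (is.null(bl)) {
    bl <- if (b >= 1) max(1, 2^floor(log2(b)) / 16) else 1
    bl <- max(1, 2^floor(log2(bl)))  # exact power of two, >= 1
  }
  stopifnot(bl >= 1, log2(bl) == floor(log2(bl)))
  prefix_bits <- as.integer(log2(bl))
  if (prefix_bits > 2 * k) stop("prefix table wider than the k-mer universe")
  ent <- .prefix_table_entries_cpp(as.numeric(X), as.integer(k),
                                   prefix_bits, bl)
  width <- max(1L, ceiling(log2(length(X) + 1)))
  structure(
    list(ell = bl / max(b, 1), bl = bl, prefix_bits = prefix_bits,
         entries = fw_encode(ent, width),
         size_bits = (bl + 1) * width),
    class = "prefix_table"
  )
}

# assemble a queryable index from plain segment arrays (shared by the
# public constructor and test fixtures)
pla_index_from_arrays <- function(X, Ystart, Yend, k, eps, N, variant,
                                  x_encoding = c("delta", "ef"),
                                  forced = 0, n = NA_real_, bl = NULL) {
  x_encoding <- match.arg(x_encoding)
  b <- length(X) - 1L
  X_enc <- if (x_encoding == "delta") delta_x_encode(X, k) else {
    ef_encode(X, 4^k)
  }
  # Ystart can dip to -eps on the first segment; shift into [0, N + 2 eps)
  Ystart_enc <- ef_encode(Ystart, N + 2 * eps, offset = -eps)
  if (variant == "basic") {
    zz <- zigzag(Yend - Ystart)
    width <- max(1L, ceiling(log2(1 + 4 * eps)))
    Yend_enc <- fw_encode(zz, width)
  } else {
    Yend_enc <- dac_encode(zigzag(Yend - Ystart))
  }
  D <- build_prefix_table(X, k, bl = bl)
  structure(
    list(k = as.integer(k), eps = eps, variant = variant, N = N, n = n,
         b = b, forced = forced, x_encoding = x_encoding,
         X_enc = X_enc, Ystart_enc = Ystart_enc, Yend_enc = Yend_enc,
         D = D, X0 = X[1], Xb = X[length(X)]),
    class = "pla_index"
  )
}

#' Build a piece-wise linear search index over a sorted k-mer list
#'
#' Fits the rank curve of S with maximal segments under error bound `eps`
#' (see [build_segments()]) and stores the result compactly: breakpoints in
#' a delta-from-uniform or Elias-Fano encoding, start values in Elias-Fano
#' (they are provably non-decreasing), end values as small deltas against
#' the start values (fixed width of `ceiling(lg(1+4*eps))` bits in the
#' basic variant, directly addressable codes in the repeat variant), plus
#' the prefix lookup table.
#'
#' @param S a `kmer_spectrum` (direct or indirect).
#' @param eps positive integer error bound; larger values give smaller
#'   indexes but wider query windows (`2*eps+1` probes worst case).
#' @param variant `"basic"` (rank and search, first occurrence within eps)
#'   or `"repeat"` (search-oriented; some occurrence within eps).
#' @param x_encoding `"delta"` (default; fastest access) or `"ef"`
#'   (Elias-Fano; smallest).
#' @return a `pla_index` object.
#' @examples
#' S <- build_spectrum(gen_genome(2000, seed = 7), 8)
#' idx <- pla_index(S, eps = 4)
#' x <- spectrum_values(S)[100]
#' pla_search(idx, S, x)
#' @export
pla_index <- function(S, eps, variant = c("basic", "repeat"),
                      x_encoding = c("delta", "ef")) {
  variant <- match.arg(variant)
  x_encoding <- match.arg(x_encoding)
  seg <- build_segments(S, eps, variant)
  pla_index_from_arrays(seg$X, seg$Ystart, seg$Yend, S$k, eps, S$N, variant,
                        x_encoding, forced = seg$forced, n = S$n)
}

#' @export
print.pla_index <- function(x, ...) {
  st <- pla_stats(x)
  cat(sprintf(
    "pla_index: %s variant, k=%d, eps=%d, N=%g, b=%d segments (%g forced)\n",
    x$variant, x$k, as.integer(x$eps), x$N, x$b, x$forced))
  cat(sprintf("  size: %.0f bits (%.2f bits/segment), X as %s\n",
              st$bits_total, st$bits_total / max(x$b, 1), x$x_encoding))
  invisible(x)
}

#' Piece-wise linear rank estimate
#'
#' Locates the segment containing `x` through the prefix table and a
#' bracketed binary search over the breakpoints, then linearly interpolates
#' between the segment's integer endpoints (integer differences first, then
#' floating multiply/divide), clamping to `[0, N-1]`.
#'
#' For every k-mer x present in the indexed list, the estimate satisfies
#' the floor-discretized error bound
#' `rank(S,x) - eps <= est < rank(S,x) + eps + 1` (repeat variant: with
#' `rank + occ - 1` as the reference), i.e. `floor(est)` is within eps of
#' an occurrence, which is what the search window and the exact variant
#' rely on.
#'
#' @param idx a `pla_index`.
#' @param x numeric vector of k-mer codes inside `[X[0], X[b]]`; codes
#'   outside return NA.
#' @return numeric vector of real-valued rank estimates.
#' @export
pla_est <- function(idx, x) {
  stopifnot(inherits(idx, "pla_index"))
  .pla_query_cpp(idx, list(), as.numeric(x), 0L)
}

#' Search for any occurrence of k-mers in S
#'
#' Probes only positions within `[floor(est-eps), ceiling(est+eps)]` of the
#' estimate, short-cutting as soon as an occurrence is hit.
#'
#' @param idx a `pla_index` built over S.
#' @param S the `kmer_spectrum` the index supplements (the index never
#'   replaces the list itself).
#' @param x numeric vector of k-mer codes.
#' @return 0-based positions in S, or -1 for absent k-mers.
#' @export
pla_search <- function(idx, S, x) {
  stopifnot(inherits(idx, "pla_index"), inherits(S, "kmer_spectrum"))
  .pla_query_cpp(idx, S, as.numeric(x), 1L)
}

#' First-occurrence rank of k-mers in S
#'
#' Basic variant: binary search inside the estimate window for the smallest
#' position with `S[i] >= x`.  Repeat variant: find any occurrence, then
#' scan backwards while the preceding value equals x.
#'
#' @inheritParams pla_search
#' @return 0-based first-occurrence positions, or -1 for absent k-mers.
#' @export
pla_rank <- function(idx, S, x) {
  if (inherits(idx, "pla_index_exact")) return(exact_rank(idx, S, x))
  stopifnot(inherits(idx, "pla_index"), inherits(S, "kmer_spectrum"))
  .pla_query_cpp(idx, S, as.numeric(x), 2L)
}

#' Size accounting for a built index
#'
#' Reports measured payload bits per component, the o(b) auxiliary bits
#' (select samples, table sentinel), and the closed-form size bound: the
#' sum of the component costs
#' `b*(lg(4^k/b) + lg(N/b) + lg(1+4*eps) + ell*lg(b) + c)`
#' evaluated at c = 4 (two Elias-Fano arrays at up to 2 extra bits per
#' element each).
#'
#' @param idx a `pla_index`.
#' @return a list of component sizes in bits.
#' @export
pla_stats <- function(idx) {
  stopifnot(inherits(idx, "pla_index"))
  bits_X <- idx$X_enc$size_bits
  bits_Ys <- idx$Ystart_enc$size_bits
  bits_Ye <- idx$Yend_enc$size_bits
  bits_D <- idx$D$size_bits
  overhead <- sum(idx$Ystart_enc$overhead_bits,
                  if (idx$x_encoding == "ef") idx$X_enc$overhead_bits else 0,
                  if (!is.null(idx$Yend_enc$overhead_bits))
                    idx$Yend_enc$overhead_bits else 0)
  list(b = idx$b, forced = idx$forced,
       bits_X = bits_X, bits_Ystart = bits_Ys, bits_Yend = bits_Ye,
       bits_D = bits_D,
       bits_total = bits_X + bits_Ys + bits_Ye + bits_D,
       overhead_bits = overhead,
       size_bound_c4 = size_bound_bits(max(idx$b, 1), idx$k, idx$N,
                                       idx$eps, idx$D$ell, cc = 4))
}

# closed-form index size: sum of the per-component costs
size_bound_bits <- function(b, k, N, eps, ell = NULL, cc = 4) {
  if (is.null(ell)) {
    bl <- max(1, 2^floor(log2(max(1, 2^floor(log2(max(b, 1))) / 16))))
    ell <- bl / max(b, 1)
  }
  b * (log2(4^k / b) + log2(pmax(N / b, 1)) + log2(1 + 4 * eps) +
         ell * log2(max(b, 2)) + cc)
}

#' Choose eps to meet a target index size
#'
#' Runs a pilot construction at eps = 256 and measures its size and segment
#' count.  The closed-form per-segment cost, with the observed segment
#' count extrapolated as `b(eps) = b_pilot * 256 / eps` (segment counts
#' scale roughly inversely with eps on genomic data), is then anchored to
#' the measured pilot size, and the smallest eps whose predicted size fits
#' `target_bytes` is returned.  The answer is a ballpark figure, clamped to
#' at least 1; a budget below the size achievable even at very large eps is
#' rejected, reporting that minimum.
#'
#' @param S a `kmer_spectrum`.
#' @param target_bytes desired index size in bytes.
#' @return the suggested integer eps.
#' @export
choose_eps <- function(S, target_bytes) {
  stopifnot(inherits(S, "kmer_spectrum"), target_bytes > 0)
  pilot_eps <- 256
  pilot <- pla_index(S, pilot_eps)
  st <- pla_stats(pilot)
  measured <- st$bits_total + st$overhead_bits
  bf <- function(eps) {
    b <- pmax(1, pilot$b * pilot_eps / eps)
    size_bound_bits(b, S$k, S$N, eps, ell = NULL, cc = 3.5)
  }
  predicted <- function(eps) measured * bf(eps) / bf(pilot_eps)
  eps_max <- 2^20
  target_bits <- target_bytes * 8
  if (predicted(eps_max) > target_bits) {
    stop(sprintf(
      "target of %.0f bytes is below the minimum achievable size (about %.0f bytes)",
      target_bytes, predicted(eps_max) / 8))
  }
  lo <- 1
  hi <- eps_max
  if (predicted(lo) <= target_bits) return(1)
  while (lo + 1 < hi) {  # predicted() is decreasing in eps
    mid <- floor((lo + hi) / 2)
    if (predicted(mid) <= target_bits) hi <- mid else lo <- mid
  }
  hi
}
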