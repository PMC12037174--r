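#' Build a minimal perfect hash function over distinct k-mer codes
#'
#' Hash-and-displace construction: keys fall into about n/3 buckets; each
#' bucket (largest first) searches for the smallest displacement seed under
#' which its keys land on distinct free slots of `[0, n)`.  Restricted to
#' the keys the map is a bijection onto `0..n-1`; any other k-mer maps to
#' an arbitrary slot, never an error.
#'
#' @param keys numeric vector of distinct k-mer codes.
#' @return an `mphf` object; `$bits_per_key` reports the packed seed-array
#'   space per key.
#' @export
build_mphf <- function(keys) {
  .mphf_build_cpp(as.numeric(keys))
}

#' Evaluate an MPHF
#'
#' @param mphf an `mphf` object.
#' @param keys numeric vector of k-mer codes (keys or non-keys).
#' @return slots in `[0, n)`; a bijection when restricted to the build keys.
#' @export
mphf_lookup <- function(mphf, keys) {
  stopifnot(inherits(mphf, "mphf"))
  .mphf_lookup_cpp(mphf, as.numeric(keys))
}

#' Build the exact index: basic index + MPHF + error array
#'
#' On top of a basic piece-wise linear index, stores for every distinct
#' k-mer x the discretized estimation error
#' `E[mphf(x)] = floor(plaEst(x)) - rank(S, x)`, which the error bound
#' guarantees lies in `[-eps, eps]` and therefore fits in
#' `ceiling(lg(2*eps+1))` bits.  A rank query then computes
#' `p = floor(plaEst(x)) - E[mphf(x)]` and needs a single probe of S to
#' confirm: p is exact by construction for members, and the probe rejects
#' non-members that alias a key's slot.
#'
#' @param S a `kmer_spectrum`.
#' @param eps positive integer error bound for the underlying basic index.
#' @return a `pla_index_exact` object.
#' @export
build_exact <- function(S, eps) {
  stopifnot(inherits(S, "kmer_spectrum"))
  base <- pla_index(S, eps, variant = "basic")
  v <- spectrum_values(S)
  d <- .distinct_ranks_cpp(v)
  est <- floor(pla_est(base, d$x))
  E_val <- est - d$rank
  if (any(abs(E_val) > eps)) {
    stop("internal error: estimation error escaped [-eps, eps]")
  }
  mphf <- build_mphf(d$x)
  slots <- mphf_lookup(mphf, d$x)
  width <- max(1L, ceiling(log2(2 * eps + 1)))
  E_store <- numeric(length(E_val))
  E_store[slots + 1] <- zigzag(E_val)
  E <- fw_encode(E_store, width)
  structure(
    list(base = base, mphf = mphf, E = E, k = S$k, eps = eps,
         n = length(d$x), N = S$N),
    class = "pla_index_exact"
  )
}

#' Exact rank via the error array
#'
#' @param idx a `pla_index_exact`.
#' @param S the `kmer_spectrum` the index supplements.
#' @param x numeric vector of k-mer codes.
#' @return exact 0-based first-occurrence ranks, or -1 for absent k-mers;
#'   exactly one probe of S per query.
#' @export
exact_rank <- function(idx, S, x) {
  stopifnot(inherits(idx, "pla_index_exact"), inherits(S, "kmer_spectrum"))
  .exact_rank_cpp(idx$base, idx$mphf, idx$E, S, as.numeric(x))
}

#' @export
print.pla_index_exact <- function(x, ...) {
  cat(sprintf(
    "pla_index_exact: k=%d, eps=%d, n=%g keys, E: %g bits, MPHF: %.2f bits/key\n",
    x$k, as.integer(x$eps), x$n, x$E$size_bits, x$mphf$bits_per_key))
  invisible(x)
}
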