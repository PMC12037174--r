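#' Generate a seeded genome with tunable repeat content
#'
#' Emits the sequence in blocks of `repeat_unit` bases: with probability
#' `repeat_fraction` a block copies an earlier window (half tandem, half
#' dispersed), otherwise it is i.i.d. uniform A/C/G/T.  Higher repeat
#' fractions raise the N/n ratio of the k-spectrum, the regime in which the
#' repeat-stretched index saves segments.  Generation uses the package's own
#' splitmix64 stream keyed only by `seed`, so the same specification always
#' yields the same genome on every platform.
#'
#' @param length genome length in bases.
#' @param repeat_fraction fraction of blocks copied from earlier sequence.
#' @param repeat_unit block length in bases.
#' @param seed integer seed.
#' @return a single character string.
#' @examples
#' g <- gen_genome(1e4, repeat_fraction = 0.5, seed = 1)
#' S <- build_spectrum(g, 21)
#' S$N / S$n  # > 1: the spectrum has repeated 21-mers
#' @export
gen_genome <- function(length, repeat_fraction = 0, repeat_unit = 500,
                       seed = 1) {
  stopifnot(length >= 1, repeat_fraction >= 0, repeat_fraction <= 1,
            repeat_unit >= 1, length >= min(repeat_unit, length))
  .gen_genome_cpp(as.numeric(length), as.numeric(repeat_fraction),
                  as.numeric(repeat_unit), as.numeric(seed))
}

#' Generate a seeded sorted k-mer list with controlled duplication
#'
#' Draws `n_distinct` distinct codes uniformly from `[0, universe)` and
#' repeats each one `1 + Geometric(dup_rate)` times, so `dup_rate = 0` gives
#' N = n and `dup_rate = 0.5` gives mean multiplicity 2.
#'
#' @param n_distinct number of distinct codes.
#' @param universe universe size; use `4^k` to make the list a valid
#'   k-spectrum.
#' @param dup_rate duplication rate in `[0, 1)`.
#' @param seed integer seed.
#' @return a direct `kmer_spectrum` (k inferred as `log4(universe)`,
#'   rounded up).
#' @export
gen_sorted_list <- function(n_distinct, universe, dup_rate = 0, seed = 1) {
  stopifnot(n_distinct >= 1, n_distinct <= universe,
            dup_rate >= 0, dup_rate < 1)
  values <- .gen_sorted_list_cpp(as.numeric(n_distinct), as.numeric(universe),
                                 as.numeric(dup_rate), as.numeric(seed))
  k <- max(1L, as.integer(ceiling(log(universe, base = 4))))
  new_spectrum_direct(values, k)
}

#' Worked-example index fragment
#'
#' A small hand-laid index over 6-bit k-mer codes (k = 3) with eps = 4 and a
#' 4-entry prefix table, arranged so that the segment spanning breakpoints
#' X[4] = 26 and X[5] = 48 carries start value 494 and end value 714.  The
#' interpolated estimate for the query code 30 is then
#' 494 + (714-494)/(48-26) * (30-26) = 534, and the eps-window a search
#' would probe is `[530, 538]`.  Indices into X here are 0-based.
#'
#' @return a list with the assembled `index`, the `X`, `Ystart`, `Yend`
#'   arrays, the query code `query`, and the expected `est` and `window`.
#' @export
fig2_fixture <- function() {
  X <- c(0, 8, 16, 21, 26, 48, 56)
  Ystart <- c(0, 120, 260, 380, 494, 710, 840)
  Yend <- c(0, 118, 262, 378, 496, 714, 842)
  idx <- pla_index_from_arrays(X, Ystart, Yend, k = 3, eps = 4, N = 850,
                               variant = "basic", x_encoding = "delta",
                               bl = 4)
  list(index = idx, X = X, Ystart = Ystart, Yend = Yend,
       query = 30, est = 534, window = c(530, 538))
}
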