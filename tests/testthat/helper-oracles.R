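# Brute-force oracles shared across tests.  These deliberately avoid the
# package's C++ code paths: everything here is plain R.

# lexicographic brute-force suffix sort, 0-based positions
brute_suffix_sort <- function(genome) {
  L <- nchar(genome)
  suf <- vapply(seq_len(L), function(i) substr(genome, i, L), character(1))
  order(suf) - 1L
}

# rank by binary search over a materialized sorted vector (first occurrence);
# -1 for absent values
rank_binary_oracle <- function(values, x) {
  lo <- findInterval(x - 0.5, values)  # values strictly below x (integers)
  hit <- lo < length(values) & values[lo + 1] == x
  ifelse(hit, lo, -1)
}

occ_binary_oracle <- function(values, x) {
  findInterval(x, values) - findInterval(x - 0.5, values)
}

# does some line fit all ranges?  Pairwise slope-window reduction (Helly),
# written independently of the C++ hull fitter
lp_feasible <- function(x, lo, hi) {
  n <- length(x)
  if (n <= 1) return(TRUE)
  A <- -Inf
  B <- Inf
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      dx <- x[i] - x[j]
      A <- max(A, (lo[i] - hi[j]) / dx)
      B <- min(B, (hi[i] - lo[j]) / dx)
    }
  }
  A <= B + 1e-12
}

# random ranged-point stream around a noisy trend
random_stream <- function(n, seed, spread = 3) {
  set.seed(seed)
  x <- cumsum(1 + rpois(n, 4))
  y <- round(x * runif(1, 0.1, 2) + rnorm(n, 0, spread))
  y <- cummax(y)
  list(x = x, lo = y - sample(0:2, n, TRUE), hi = y + sample(0:2, n, TRUE))
}

# deployed-guarantee margins of an index over the distinct k-mers of S:
# c(worst lo - est, worst est - hi); the shipped bound requires
# margin[1] <= 0 and margin[2] < 1
guarantee_margins <- function(idx, S) {
  d <- plaindex:::.distinct_ranks_cpp(spectrum_values(S))
  plaindex:::.guarantee_margins_cpp(idx, d$x, d$rank, d$occ)
}

expect_index_invariants <- function(S, eps, x_encoding = "delta") {
  seg_b <- build_segments(S, eps, "basic")
  seg_r <- build_segments(S, eps, "repeat")
  # monotone start values (Elias-Fano encodability)
  expect_true(!is.unsorted(seg_b$Ystart))
  expect_true(!is.unsorted(seg_r$Ystart))
  # basic-variant endpoint deltas bounded by 2 eps
  expect_true(all(abs(seg_b$Yend - seg_b$Ystart) <= 2 * eps))
  # repeat stretching never adds segments
  expect_lte(seg_r$b, seg_b$b)
  # deployed guarantee for both variants
  ib <- pla_index(S, eps, "basic", x_encoding)
  ir <- pla_index(S, eps, "repeat", x_encoding)
  mb <- guarantee_margins(ib, S)
  mr <- guarantee_margins(ir, S)
  expect_lte(mb[1], 0)
  expect_lt(mb[2], 1)
  expect_lte(mr[1], 0)
  expect_lt(mr[2], 1)
  invisible(list(basic = ib, repeat_ = ir,
                 seg_basic = seg_b, seg_repeat = seg_r))
}
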