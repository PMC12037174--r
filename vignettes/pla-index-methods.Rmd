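---
title: "Piece-wise linear k-mer indexes: model, guarantees and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piece-wise linear k-mer indexes: model, guarantees and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaindex)
```

## The model

Let S be a list of N k-mers sorted in non-decreasing order, with n distinct
values, and identify each k-mer with its base-4 code (A=0, C=1, G=2, T=3;
codes are kept in doubles, exact up to k = 26).  For a k-mer x of the
universe, rank(S, x) is the position of its first occurrence in S, and −1
when absent.  The index approximates the rank curve x → rank(S, x) with a
piece-wise linear function: strictly increasing breakpoint k-mers
X[0..b], integer start values Ystart[0..b] and end values Yend[0..b], where
segment i runs from (X[i], Ystart[i]) to (X[i+1], Yend[i+1]) and a query
inside it is answered by linear interpolation (`pla_est`).  A local search
over the window `[floor(est − eps), ceiling(est + eps)]` of S then answers
`search` and `rank`.  The index supplements S; it never replaces it.

Assumptions worth making explicit: S fits in memory (directly or as a
suffix array over the genome), k ≤ 26, and queries are single k-mers (no
batch sharing beyond vectorization).  Nothing assumes the rank curve is
actually near-linear — a jagged curve simply yields more segments.

## The streaming fitter

Each distinct k-mer x contributes an admissible y-range: [rank − ε,
rank + ε] in the basic variant, widened to [rank − ε, rank + ε + occ(x) − 1]
under repeat stretching (any occurrence, not necessarily the first, may be
predicted).  A line y = m·x + c *fits* a set of ranged points if its value
at every x lies inside that point's range.  Eliminating c turns existence
of a fitting line into pairwise slope conditions

    (lo_i − hi_j)/(x_i − x_j)  ≤  m  ≤  (hi_i − lo_j)/(x_i − x_j),  j < i,

(one-dimensional Helly property), so the fitter maintains the feasible
slope interval [A, B].  When a point arrives, the new bounds are tangents
from its range endpoints to two convex hulls of the earlier endpoints,
located by binary search; all comparisons are exact 128-bit integer cross
products, so feasibility decisions are never corrupted by floating point.
A segment is closed only when the next point admits no line — the greedy
segments are maximal, which makes their number b minimal for the data and
ε.  The test suite verifies this against an independent dynamic program
over break positions with per-piece pairwise-LP feasibility
(`min_segments_oracle`), and verifies the per-point feasibility decisions
against a plain-R LP oracle.

In the basic variant the closing k-mer is re-fed as the next segment's
opening point (shared breakpoints), which is what bounds
|Yend[i] − Ystart[i]| ≤ 2ε and enables the fixed-width Yend encoding.
Under repeat stretching the k-mer is not reused (the 2ε bound is lost
anyway; Yend moves to variable-width codes), which saves a few more
segments.

## Integer endpoints: the discretized guarantee

The stored Ystart/Yend are integers, so the deployed line's slope is
quantized in units of 1/(X[i+1] − X[i]).  The set of integer endpoint pairs
that keep every covered point strictly inside its range is the integer
lattice intersected with the feasible polygon of real lines — and at
maximal reach that polygon is routinely thinner than one lattice unit, so
insisting on the strict real-valued bound |est − rank| ≤ ε would force
early terminations on a large fraction of segments and inflate b well past
the optimum.

What the queries actually consume is weaker, and this is the guarantee the
package ships:

    rank − ε  ≤  est(x)  <  rank + ε + 1        (basic; floor(est) within ±ε)
    rank − ε  ≤  est(x)  <  rank + occ − 1 + ε + 1   (repeat)

It is exactly the condition under which the floor/ceiling search window
contains an occurrence, and exactly the condition the exact variant needs
so that `floor(est) − rank` fits a ⌈lg(2ε+1)⌉-bit error entry.  Crucially,
rounding *up* both endpoint values of any feasible real line perturbs every
interpolated value by an amount in [0, 1), which keeps the lower bound and
stays under the +1 allowance — so an integer line satisfying the
discretized guarantee always exists at full greedy reach, and segment
counts are unaffected by integer storage.

The closer therefore works in two phases: it first looks for an integer
pair meeting the strict ranges (preserving the tighter bound when the
lattice allows it), then falls back to the discretized relaxation.  Within
the accepted phase it picks the feasible Ystart closest to the true rank at
the segment start, restricted to Ystart ≤ rank(x_end) − ε, and the Yend
closest to the rank at the breakpoint.  The restriction costs nothing:
when rank(x_end) − rank(x_start) ≥ 2ε every feasible start value is below
it, and otherwise the explicit integer line through (x_start,
rank(x_end) − ε) and (x_end, rank(x_start) + ε) fits.  It buys the key
structural fact that consecutive Ystart values never decrease — segment
i+1 must start at or above rank(X[i+1]) − ε, which is at or above segment
i's capped start — so Ystart is Elias-Fano encodable.  Centring on the
rank curve also makes the stored line track the data (a perfectly linear
list stores the exact line and an all-zero exact-variant error array).

Every closed segment is re-verified point by point with the same
double-precision interpolation the query path uses (integer differences
first, then floating multiply/divide, clamped to [0, N−1]).  If
floating-point rounding lands a value outside the discretized bound — a
corner case the exact integer search cannot see — the segment is
terminated at the last verified k-mer and construction restarts there;
these are the *forced* breaks, counted in `$forced`.  On all synthetic
builds exercised by the tests the count is zero; the suite asserts
forced/b ≤ 1%.

A segment left with a single distinct k-mer stores a zero-slope line at
rank − ε (the minimal feasible value; storing the rank itself could break
the monotone-Ystart property when the following segment starts lower).

## Compact storage

* **X** — default is the delta-from-uniform encoding: entry i stores
  X[i] − ⌊i·4^k/m⌋, bias-shifted non-negative, at the constant width of
  the largest difference.  Reconstruction is exact, access is a few bit
  operations, and the size sits between Elias-Fano and the naive 2k bits
  per breakpoint.  Elias-Fano is available via `x_encoding = "ef"`.
* **Ystart** — Elias-Fano over the universe N + 2ε, shifted by +ε so the
  first segment's value (as low as −ε) stays non-negative.  The low-bit
  width is ⌊lg(U/m)⌋, which keeps the payload under m·lg(U/m) + 2m + O(1)
  bits; select samples (one 64-bit position every 256 set bits) are
  accounted separately as overhead.
* **Yend** — basic variant: the signed delta Yend[i] − Ystart[i] (bounded
  by 2ε) is mapped to a non-negative value by 2|d| + t (t = 1 iff d > 0)
  and packed at ⌈lg(1+4ε)⌉ bits.  Repeat variant: the same transform into
  directly addressable codes (4-bit payload layers with continuation bits
  and per-word rank samples), since occ(x) can make the delta large while
  it usually stays small.
* **D** — the prefix lookup table: b·ℓ entries (ℓ = 2^⌊lg b⌋/(16b), so bℓ
  is a power of two near b/16, clamped to ≥ 1) where entry i is the
  smallest j with the top lg(bℓ) bits of X[j] at least i, plus a sentinel.
  A query extracts its top bits y and binary-searches X only in
  [D[y]−1, D[y+1]); the −1 widening makes the bracket correct whether the
  table's "at least" is read as "equal" or not.

`pla_stats` reports measured bits per component next to the closed-form
per-segment cost lg(4^k/b) + lg(N/b) + lg(1+4ε) + ℓ·lg b + c at c = 4; the
accounting test allows 2 bits per segment plus a constant on top of the
bound for integer ceilings (the Yend width, the table's ⌈lg b⌉) and the
o(b) sampling structures.  Serialization (`pla_serialize`) is bit-exact and
tagged; truncated or cross-variant files fail with named errors.

## Choosing ε from a memory budget

`choose_eps` builds a pilot index at ε = 256, then anchors the closed-form
cost to the pilot's measured size with the observed segment count
extrapolated as b(ε) = b_pilot · 256/ε (segment counts scale roughly
inversely with ε on genomic data), and bisects for the smallest ε whose
predicted size meets the budget.  The answer is deliberately a ballpark:
the ratio drifts with the data, but the self-consistency contract (a budget
equal to the pilot's own size returns ε ≈ 256) and monotonicity (more
memory never raises ε) hold, and infeasible budgets are rejected with the
approximate minimum achievable size.

## The exact variant

`build_exact` constructs the basic index, a minimal perfect hash function
over the n distinct k-mers (hash-and-displace: ~n/3 buckets, per-bucket
displacement seeds searched largest-bucket-first, seeds packed at the
width of the largest one — a few bits per key at this scale), and the
error array E[mphf(x)] = ⌊plaEst(x)⌋ − rank(S, x), each entry within
[−ε, ε] by the discretized guarantee.  `exact_rank` computes
p = ⌊plaEst(x)⌋ − E[mphf(x)] and probes S once: members get their exact
first-occurrence rank, non-members fail the probe and return −1.  Raising
ε shrinks the PLA component but widens E at ⌈lg(2ε+1)⌉ bits per key; the
suite asserts both monotone trends and that bits(E) = n·⌈lg(2ε+1)⌉ exactly.

## Synthetic data

All tests run on generated data; nothing is downloaded.

* `gen_genome` emits blocks of `repeat_unit` bases, each either uniform
  random or (with probability `repeat_fraction`) a copy of an earlier
  window, half tandem and half dispersed.  That makes N/n — the driver of
  repeat stretching — tunable: at k = 21, repeat_fraction 0 gives
  N/n ≈ 1.00 and 0.5 gives N/n ≈ 1.9 at the sizes used here.  The
  generator uses the package's own splitmix64 stream keyed by the seed, so
  outputs are identical across platforms and no global RNG state is
  touched.
* `gen_sorted_list` draws distinct codes uniformly and duplicates each one
  geometrically (`dup_rate` 0.5 gives mean multiplicity 2), for direct
  control over list density and duplication.
* `fig2_fixture` lays out a small index fragment by hand (k = 3, ε = 4, a
  4-entry prefix table, and a segment from breakpoint 26 with value 494 to
  breakpoint 48 with value 714) whose interpolated estimate at query code
  30 is exactly 534; it anchors the documentation example and the
  acceptance computation.

What the generators do *not* emulate: base-composition and dinucleotide
bias, long segmental duplications, and chromosome-scale heterogeneity of
real genomes.  Uniform random sequence produces an almost perfectly linear
rank curve, which is the *easy* case for segment counts (few, long
segments) but the *adversarial* case for integer endpoint storage (thin
feasible polygons).  Passing tests therefore demonstrate correctness and
the guarantees' invariants, not the absolute segment counts one would
measure on a real assembly.

## Numerical choices

* K-mer codes and list positions are doubles holding exact integers
  (≤ 2^53); all index arithmetic that affects correctness is exact 64/128
  bit integer work in C++.
* `pla_est` computes integer differences first and multiplies in doubles;
  construction re-verifies with this exact routine, so the shipped
  guarantee is the deployed one.
* Estimates are clamped to [0, N−1]; queries below X[0] or above X[b]
  return −1 outright, and x = X[b] returns Ystart[b], which is stored as
  the true rank of the largest k-mer.
* Yend values at breakpoints are the closing line extrapolated to the next
  segment's opening k-mer (repeat variant) or evaluated at the shared
  breakpoint (basic), so queries reproduce the fitted line exactly under
  the interpolation formula.
* Ties in the endpoint search break toward smaller Ystart; the Yend target
  rounds half away from negative infinity.
* All indices and positions are 0-based throughout, matching the
  formulas; ranges are half-open unless stated.

## Problem sizes in the test suite

The suite builds: exhaustive checks over every ACGT genome of length ≤ 10
at k = 2 (1.4 million genomes, in compiled code); 1,000 random lists up to
N = 10^4 for the guarantee; 1,000 random instances (N ≤ 500, universe 4^8)
for piece-count optimality against the DP oracle; full-universe oracle
equivalence for k ≤ 6; and a 1 Mb genome at k = 21 with 10^5 mixed queries
for all three variants over both direct and suffix-array-indirect lists.
The whole suite runs in under two minutes on one core.

## Limitations

* No reverse-complement canonicalization — the literal k-mers are indexed.
* Suffix-array construction is an in-memory prefix-doubling builder,
  O(L lg² L): fine for megabase-scale experiments, not for full mammalian
  assemblies.
* The repeat variant supports `rank` by scanning backwards over equal
  k-mers; with an indirect (suffix array) list every step is a cache miss,
  so that combination is best reserved for `search`-dominated workloads.
* `choose_eps` is a calibrated heuristic, not an optimizer.
* Construction is single-threaded and in-memory.
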