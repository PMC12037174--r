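# plaindex

Error-bounded piece-wise linear search indexes for sorted k-mer lists, in R.

## The problem

K-mer based methods keep their data as a sorted list S of k-mers — the
k-spectrum of a genome stored directly as integer codes, or indirectly
through the genome's suffix array.  Locating a query k-mer in S (`search`:
any occurrence; `rank`: the first occurrence, i.e. the number of strictly
smaller entries) is the inner loop of suffix-array lookup, seed anchoring in
read alignment, and direct-access rank tables.  Plain binary search needs no
index but takes Θ(lg N) cache-unfriendly probes.

The *rank curve* of S maps every k-mer x of the universe [0, 4^k) to
rank(S, x).  On genomic data this curve is strikingly close to linear, so it
can be approximated by a small piece-wise linear function (PLA) with a hard
error bound ε: segments are breakpoint k-mers X[0..b] with integer values
Ystart and Yend, and a query evaluates

    plaEst(x) = Ystart[i] + (Yend[i+1] − Ystart[i]) · (x − X[i]) / (X[i+1] − X[i])

for the segment with X[i] ≤ x < X[i+1], then inspects only the window
S[⌊plaEst−ε⌋ .. ⌈plaEst+ε⌉] — at most 2ε+3 positions.  The fitter is an
online convex-feasibility algorithm (exact integer arithmetic) that emits
provably maximal segments, so b is the minimum possible for the data and ε.
Segments are stored succinctly: breakpoints as constant-width deltas from a
uniform grid (or Elias-Fano), start values in Elias-Fano (they are provably
non-decreasing), end values as ≤ 2ε deltas against the start values, plus a
small prefix lookup table D that brackets the breakpoint binary search by
the query's top bits.

Three variants:

* **basic** — `search` and `rank`, first occurrence within ε;
* **repeat** — each k-mer's admissible range is widened by its multiplicity,
  so any occurrence may be predicted; fewer segments on repetitive genomes
  (`rank` then backs up to the first occurrence);
* **exact** — a minimal perfect hash function over the n distinct k-mers
  plus an error array E of n entries of ⌈lg(2ε+1)⌉ bits storing
  `⌊plaEst(x)⌋ − rank(S,x)`; `rank` becomes a single probe of S.

## Worked example

```r
library(plaindex)

genome <- gen_genome(5e5, repeat_fraction = 0.4, repeat_unit = 400, seed = 11)
S <- build_spectrum(genome, 21)
S
#> kmer_spectrum: k=21, N=499980, n=306382 (direct, N/n=1.632)

idx <- pla_index(S, eps = 63, variant = "repeat")
idx
#> pla_index: repeat variant, k=21, eps=63, N=499980, b=107 segments (0 forced)
#>   size: 6829 bits (63.82 bits/segment), X as delta

q <- encode_kmer(substr(genome, 1001, 1021))
pla_est(idx, q)        # 249236  -- real-valued estimate of the position
pla_search(idx, S, q)  # 249276  -- some occurrence (|est - hit| <= eps)
pla_rank(idx, S, q)    # 249271  -- first occurrence
occ_count(S, q)        # 11      -- this 21-mer sits in a repeat

ex <- build_exact(S, 63)
exact_rank(ex, S, q)   # 249271  -- one probe of S, no local search
```

The half-megabase spectrum occupies ~4 MB as a plain array; the
repeat-stretched index that narrows every lookup to a 127-position window
serializes to 1356 bytes (`pla_serialize(idx)`).  All positions are
0-based; a `rank`/`search` of −1 means the k-mer is absent.

A thin command-line wrapper is installed as `exec/pla`
(`pla build / query / stats / synth`); see `?pla_cli`.

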