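#' Streaming line fitter over ranged points
#'
#' Creates an online fitter for points `(x, [lo, hi])` presented with
#' strictly increasing x.  The fitter maintains whether some line passes
#' within every range seen so far, using exact integer arithmetic on the
#' pairwise slope bounds (two convex hulls of range endpoints), so
#' feasibility decisions are never corrupted by floating point.
#'
#' @return an opaque fitter object for [fitter_add()] / [fitter_extract_line()].
#' @seealso [build_segments()] for the full construction loop.
#' @export
fitter_new <- function() {
  structure(list(ptr = .fitter_new_cpp()), class = "pla_fitter")
}

#' Feed one ranged point to a fitter
#'
#' @param f a fitter from [fitter_new()].
#' @param x x-value (k-mer code), strictly greater than all previous x.
#' @param lo,hi admissible y-range at x (`lo <= hi`).
#' @return `TRUE` if some line still fits every point including this one;
#'   `FALSE` if adding the point makes fitting infeasible (the fitter state
#'   is left unchanged in that case).
#' @export
fitter_add <- function(f, x, lo, hi) {
  stopifnot(inherits(f, "pla_fitter"))
  .fitter_add_cpp(f$ptr, as.numeric(x), as.numeric(lo), as.numeric(hi))
}

#' Extract the fitted line with the minimal start value
#'
#' Among all lines that fit the streamed ranges, returns the one whose value
#' at the first point is minimal (attained at the maximal feasible slope).
#' This choice guarantees that consecutive segment start values are
#' non-decreasing, which the index's monotone start-value encoding requires.
#'
#' @param f a fitter with at least one point in a feasible state.
#' @return list with `x_first`, `x_last`, `y_first`, `y_last` (real values
#'   of the line at the first and last fitted points, before rounding).
#' @export
fitter_extract_line <- function(f) {
  stopifnot(inherits(f, "pla_fitter"))
  .fitter_extract_cpp(f$ptr)
}

#' Number of points currently fitted
#' @param f a fitter.
#' @return point count.
#' @export
fitter_size <- function(f) .fitter_size_cpp(f$ptr)

#' Build a maximal-segment piece-wise linear approximation of the rank curve
#'
#' Streams the distinct k-mers of S with y-ranges `[rank - eps, rank + eps]`
#' (basic variant) or `[rank - eps, rank + eps + occ - 1]` (repeat variant,
#' which lets the estimate point at any occurrence and so needs fewer
#' segments on repetitive data).  A segment is closed only when the next
#' k-mer makes fitting infeasible; the basic variant re-feeds the closing
#' k-mer as the next segment's opening point so consecutive end/start values
#' stay within 2*eps of each other.  Endpoints are stored as integers: the
#' closer searches for the integer endpoint pair with the smallest feasible
#' start value under the floor-discretized guarantee
#' `floor(est(x))` in `[rank - eps, rank + eps]` (which is exactly what the
#' query window and the exact variant's error array consume; rounding any
#' feasible real line's endpoints up always satisfies it, so such a pair
#' always exists at full reach).  Every covered k-mer is then re-verified
#' with the deployed double-precision interpolation arithmetic; in the rare
#' floating-point corner case where verification fails, the segment is
#' terminated early at the last verified k-mer (a "forced" break) and
#' construction restarts there.
#'
#' @param S a `kmer_spectrum`.
#' @param eps positive integer error bound.
#' @param variant `"basic"` or `"repeat"`.
#' @return a `segment_set`: breakpoint codes `X` (length b+1), integer
#'   `Ystart` and `Yend` (length b+1; `Yend[1]` mirrors `Ystart[1]`),
#'   segment count `b`, forced-break count `forced`.
#' @export
build_segments <- function(S, eps, variant = c("basic", "repeat")) {
  variant <- match.arg(variant)
  stopifnot(inherits(S, "kmer_spectrum"))
  if (!is.numeric(eps) || length(eps) != 1 || eps < 1 || eps != floor(eps)) {
    stop("eps must be a positive integer (eps >= 1)")
  }
  v <- spectrum_values(S)
  if (length(v) == 0) stop("cannot build segments over an empty list")
  d <- .distinct_ranks_cpp(v)
  r <- .build_segments_cpp(d$x, d$rank, d$occ, eps,
                           if (variant == "repeat") 1L else 0L, length(v))
  structure(
    list(X = r$X, Ystart = r$Ystart, Yend = r$Yend,
         b = length(r$X) - 1L, forced = r$forced,
         variant = variant, eps = eps, N = length(v), k = S$k),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %s variant, eps=%d, b=%d segments (%d forced)\n",
              x$variant, as.integer(x$eps), x$b, as.integer(x$forced)))
  invisible(x)
}

#' Exact minimum piece count for ranged points (test oracle)
#'
#' Dynamic program over break positions with an independent pairwise-slope
#' (Helly) feasibility check per piece, sharing no code with the streaming
#' fitter.  `mode = "shared"` makes adjacent pieces share their boundary
#' point (basic-variant semantics); `mode = "partition"` partitions the
#' points, with a lone trailing point folding into the final breakpoint
#' (repeat-variant semantics).
#'
#' @param x strictly increasing x-values.
#' @param lo,hi per-point ranges.
#' @param mode `"shared"` or `"partition"`.
#' @return minimum number of pieces.
#' @export
min_segments_oracle <- function(x, lo, hi, mode = c("shared", "partition")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(lo), length(lo) == length(hi))
  .min_segments_oracle_cpp(as.numeric(x), as.numeric(lo), as.numeric(hi),
                           if (mode == "shared") 0L else 1L)
}
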