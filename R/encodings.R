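#' Elias-Fano encoding of a non-decreasing integer sequence
#'
#' Stores m non-decreasing values from a universe of size U in about
#' `m*lg(U/m) + 2m` bits with constant-time random access.  Values may be
#' shifted by `offset` before encoding (used internally to store start
#' values that can be as low as `-eps`).
#'
#' @param values non-decreasing numeric vector.
#' @param U universe size: all shifted values must lie in `[0, U)`.
#' @param offset signed shift subtracted before encoding (default 0).
#' @return an `ef_seq` object.
#' @export
ef_encode <- function(values, U, offset = 0) {
  .ef_encode_cpp(as.numeric(values), as.numeric(U), as.numeric(offset))
}

#' Random access into an Elias-Fano sequence
#' @param seq an `ef_seq`.
#' @param i 0-based indices.
#' @return the stored values.
#' @export
ef_access <- function(seq, i) {
  stopifnot(inherits(seq, "ef_seq"))
  .ef_access_cpp(seq, as.numeric(i))
}

#' Payload size of an Elias-Fano sequence in bits
#'
#' Counts the low-bit and high-bit payload; the o(m) select samples are
#' reported separately in `seq$overhead_bits`.
#'
#' @param seq an `ef_seq`.
#' @return bits used.
#' @export
ef_size_bits <- function(seq) {
  stopifnot(inherits(seq, "ef_seq"))
  seq$size_bits
}

#' Delta-from-uniform encoding of breakpoint k-mers
#'
#' If the m breakpoints were spread evenly over the `4^k` universe, entry i
#' would be `floor(i*4^k/m)`; only the (bias-shifted) difference from that
#' value is stored, at the constant width needed for the largest difference.
#' Reconstruction is exact.  On genomic data this sits between Elias-Fano
#' and the naive 2k-bit encoding in size, with cheaper access than
#' Elias-Fano.
#'
#' @param X strictly increasing k-mer codes.
#' @param k k-mer length.
#' @return a `dxu_seq` object.
#' @export
delta_x_encode <- function(X, k) {
  .dxu_encode_cpp(as.numeric(X), as.integer(k))
}

#' Random access into a delta-from-uniform sequence
#' @param seq a `dxu_seq`.
#' @param i 0-based indices.
#' @return the stored k-mer codes.
#' @export
delta_x_access <- function(seq, i) {
  stopifnot(inherits(seq, "dxu_seq"))
  .dxu_access_cpp(seq, as.numeric(i))
}

#' Map signed integers to non-negatives (and back)
#'
#' The transform is `2*|d| + t` with `t = 1` if d is positive and 0
#' otherwise, so small magnitudes stay small; variable-width codes can then
#' store signed deltas.
#'
#' @param d signed integers.
#' @return non-negative integers.
#' @export
zigzag <- function(d) {
  ifelse(d > 0, 2 * abs(d) + 1, 2 * abs(d))
}

#' @rdname zigzag
#' @param z non-negative integers produced by [zigzag()].
#' @export
unzigzag <- function(z) {
  ifelse(z %% 2 == 1, (z - 1) / 2, -z / 2)
}

#' Directly addressable codes for non-negative integers
#'
#' Variable-width encoding with random access: values are cut into
#' `width`-bit chunks across layers, with a continuation bit per entry and
#' rank samples for addressing.  Small values use one chunk; the total never
#' exceeds fixed-width storage at the maximum value by more than the
#' continuation bits.
#'
#' @param values non-negative integers (zigzag-transform signed data first).
#' @param width payload bits per layer (default 4).
#' @return a `dac_seq` object.
#' @export
dac_encode <- function(values, width = 4) {
  .dac_encode_cpp(as.numeric(values), as.integer(width))
}

#' Random access into a DAC sequence
#' @param seq a `dac_seq`.
#' @param i 0-based indices.
#' @return the stored values.
#' @export
dac_access <- function(seq, i) {
  stopifnot(inherits(seq, "dac_seq"))
  .dac_access_cpp(seq, as.numeric(i))
}

#' Fixed-width bit packing
#'
#' @param values non-negative integers `< 2^width`.
#' @param width bits per entry (1..56).
#' @return an `fw_seq` object.
#' @export
fw_encode <- function(values, width) {
  .fw_encode_cpp(as.numeric(values), as.integer(width))
}

#' Random access into a fixed-width sequence
#' @param seq an `fw_seq`.
#' @param i 0-based indices.
#' @return the stored values.
#' @export
fw_access <- function(seq, i) {
  stopifnot(inherits(seq, "fw_seq"))
  .fw_access_cpp(seq, as.numeric(i))
}
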