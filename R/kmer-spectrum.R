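#' Encode k-mers as integer codes
#'
#' Maps a DNA string of length k to its base-4 expansion with A=0, C=1, G=2,
#' T=3 (case-insensitive).  The map is order-preserving: lexicographic order
#' of strings of equal length equals numeric order of codes.
#'
#' @param seq character vector of k-mers (all the same length).
#' @return numeric vector of codes in `[0, 4^k)`.
#' @examples
#' encode_kmer(c("AAA", "TTT", "GC"))
#' @export
encode_kmer <- function(seq) {
  stopifnot(is.character(seq))
  .encode_kmers_cpp(seq)
}

#' Decode integer codes back to k-mer strings
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k k-mer length in bases.
#' @return character vector; `encode_kmer(decode_kmer(c, k))` equals `c`.
#' @export
decode_kmer <- function(code, k) {
  stopifnot(is.numeric(code), k >= 1, k <= 26)
  if (any(code < 0 | code >= 4^k)) {
    stop("code out of range [0, 4^", k, ")")
  }
  .decode_kmers_cpp(as.numeric(code), as.integer(k))
}

new_spectrum_direct <- function(values, k) {
  n <- if (length(values)) sum(c(TRUE, diff(values) > 0)) else 0L
  structure(
    list(values = values, k = as.integer(k), N = length(values), n = n,
         representation = "direct"),
    class = "kmer_spectrum"
  )
}

#' Build the sorted k-spectrum of a genome
#'
#' All length-k windows made only of A/C/G/T (case-insensitive) are encoded
#' and sorted; windows containing any other character are skipped entirely.
#' A character vector is treated as multiple records (e.g. FASTA sequences)
#' whose spectra are merged; no window spans a record boundary.
#'
#' @param genome character vector of one or more DNA sequences.
#' @param k k-mer length (1..26).
#' @return a `kmer_spectrum` object with fields `values` (sorted codes),
#'   `k`, `N` (list length), `n` (distinct k-mers), `representation`.
#' @examples
#' S <- build_spectrum("GCCACC", 2)
#' S$N  # 5
#' S$n  # 4
#' @export
build_spectrum <- function(genome, k) {
  stopifnot(is.character(genome), length(genome) >= 1, k >= 1, k <= 26)
  if (all(nchar(genome) < k)) {
    stop("genome shorter than k = ", k)
  }
  codes <- unlist(lapply(unname(genome),
                         function(g) .spectrum_codes_cpp(g, as.integer(k))))
  new_spectrum_direct(sort(codes), k)
}

#' Build the suffix array of a genome
#'
#' Positions (0-based) of all suffixes, sorted lexicographically; non-ACGT
#' characters rank above T.  Uses an in-memory prefix-doubling construction.
#'
#' @param genome a single DNA string.
#' @return a `suffix_array` object with fields `sa` (0-based positions) and
#'   `genome`.
#' @examples
#' build_suffix_array("ACAC")$sa  # 2 0 3 1
#' @export
build_suffix_array <- function(genome) {
  stopifnot(is.character(genome), length(genome) == 1, nchar(genome) >= 1)
  structure(list(sa = .suffix_array_cpp(genome), genome = genome),
            class = "suffix_array")
}

#' View a suffix array as a sorted k-mer list
#'
#' The suffix array is an indirect representation of the k-spectrum: entry i
#' points at the genome position where the i-th smallest k-mer starts.
#' Suffixes shorter than k and windows containing non-ACGT characters are
#' excluded, so reading all entries yields exactly `build_spectrum(genome, k)`.
#'
#' @param sa a `suffix_array` object.
#' @param k k-mer length.
#' @return a `kmer_spectrum` with `representation = "indirect"`; k-mer codes
#'   are computed on demand from the genome.
#' @export
spectrum_view <- function(sa, k) {
  stopifnot(inherits(sa, "suffix_array"), k >= 1, k <= 26)
  g <- sa$genome
  L <- nchar(g)
  keep <- sa$sa <= L - k
  pos <- sa$sa[keep]
  # drop windows containing ambiguous bases; order is preserved
  codes <- .sa_spectrum_codes_cpp(g, sa$sa, as.integer(k))
  n <- if (length(codes)) sum(c(TRUE, diff(codes) > 0)) else 0L
  valid <- length(codes)
  if (valid < length(pos)) {
    # recompute kept positions exactly as the C++ filter does
    pos <- pos[vapply(pos, function(p) {
      w <- substr(g, p + 1, p + k)
      grepl("^[ACGTacgt]+$", w)
    }, logical(1))]
  }
  structure(
    list(genome = g, pos = as.integer(pos), k = as.integer(k),
         N = length(pos), n = n, representation = "indirect"),
    class = "kmer_spectrum"
  )
}

#' Materialize the codes of a k-mer spectrum
#'
#' @param S a `kmer_spectrum` (direct or indirect).
#' @return numeric vector of sorted k-mer codes.
#' @export
spectrum_values <- function(S) {
  stopifnot(inherits(S, "kmer_spectrum"))
  if (S$representation == "direct") S$values
  else .sa_spectrum_codes_cpp(S$genome, S$pos, S$k)
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, N=%d, n=%d (%s, N/n=%.3f)\n",
              x$k, x$N, x$n, x$representation,
              if (x$n > 0) x$N / x$n else NA_real_))
  invisible(x)
}

#' Rank of a k-mer in a sorted list (linear-scan test oracle)
#'
#' Returns the first position (0-based) of `x` in S, or -1 when absent.
#'
#' @param S a `kmer_spectrum`.
#' @param x numeric vector of k-mer codes.
#' @return numeric vector of positions or -1.
#' @examples
#' S <- build_spectrum("GCCACC", 2)
#' rank_oracle(S, encode_kmer(c("CC", "AC", "AG")))  # 2 0 -1
#' @export
rank_oracle <- function(S, x) {
  v <- spectrum_values(S)
  m <- match(x, v)
  ifelse(is.na(m), -1, m - 1)
}

#' Number of occurrences of a k-mer in a sorted list
#'
#' @param S a `kmer_spectrum`.
#' @param x numeric vector of k-mer codes.
#' @return numeric vector of counts (0 when absent).
#' @export
occ_count <- function(S, x) {
  v <- spectrum_values(S)
  vapply(x, function(xx) sum(v == xx), numeric(1))
}

#' Read a (multi-record) FASTA file as character sequences
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs character vector of sequences (names become record headers).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read query k-mers from a plain-text file
#'
#' One k-mer per line, either as an ACGT string or a decimal code.
#'
#' @param path text file path.
#' @param k k-mer length (used to validate codes and decode strings).
#' @return numeric vector of k-mer codes.
#' @export
read_kmer_queries <- function(path, k) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  is_code <- grepl("^[0-9]+$", lines)
  out <- numeric(length(lines))
  if (any(is_code)) out[is_code] <- as.numeric(lines[is_code])
  if (any(!is_code)) out[!is_code] <- encode_kmer(lines[!is_code])
  if (any(out < 0 | out >= 4^k)) stop("query code outside the k-mer universe")
  out
}
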