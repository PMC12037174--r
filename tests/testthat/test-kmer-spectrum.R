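test_that("k-mer codes are the base-4 expansion and round-trip exactly", {
  expect_equal(encode_kmer(c("AAA", "TTT")), c(0, 63))
  expect_equal(encode_kmer("GC"), 9)  # 2*4 + 1
  expect_equal(decode_kmer(c(0, 63), 3), c("AAA", "TTT"))
  expect_equal(decode_kmer(9, 2), "GC")
  expect_error(encode_kmer("ACNT"), "position 3")
  expect_error(decode_kmer(64, 3), "out of range")
  # lowercase accepted
  expect_equal(encode_kmer("acgt"), encode_kmer("ACGT"))
  # exhaustive round trip at k = 8
  codes <- 0:(4^8 - 1)
  expect_equal(encode_kmer(decode_kmer(codes, 8)), codes)
})

test_that("encoding preserves lexicographic order (exhaustive k <= 5)", {
  for (k in c(2, 5)) {
    strs <- decode_kmer(0:(4^k - 1), k)
    expect_false(is.unsorted(strs))        # codes ascending => strings sorted
    expect_equal(order(strs), seq_along(strs))
  }
})

test_that("build_spectrum matches the worked 2-spectrum example", {
  S <- build_spectrum("GCCACC", 2)
  expect_equal(S$N, 5)
  expect_equal(S$n, 4)
  expect_equal(decode_kmer(spectrum_values(S), 2),
               c("AC", "CA", "CC", "CC", "GC"))
  S2 <- build_spectrum("AAAA", 2)
  expect_equal(spectrum_values(S2), c(0, 0, 0))
  expect_equal(S2$n, 1)
})

test_that("windows containing ambiguous bases are skipped", {
  S <- build_spectrum("ACNGT", 2)
  expect_equal(S$N, 2)
  expect_equal(decode_kmer(spectrum_values(S), 2), c("AC", "GT"))
  # oracle: enumerate windows by hand
  g <- "ACGTNNACGNT"
  wins <- substring(g, 1:(nchar(g) - 2), 3:nchar(g))
  wins <- wins[grepl("^[ACGT]+$", wins)]
  expect_equal(spectrum_values(build_spectrum(g, 3)),
               sort(encode_kmer(wins)))
})

test_that("multi-record spectra merge without spanning record boundaries", {
  merged <- build_spectrum(c("GCCA", "ACC"), 2)
  ref <- sort(c(spectrum_values(build_spectrum("GCCA", 2)),
                spectrum_values(build_spectrum("ACC", 2))))
  expect_equal(spectrum_values(merged), ref)
  expect_error(build_spectrum("ACG", 5), "shorter than k")
})

test_that("suffix array matches brute-force sort (exhaustive 2-letter)", {
  expect_equal(build_suffix_array("ACAC")$sa, c(2L, 0L, 3L, 1L))
  expect_equal(build_suffix_array("AAAA")$sa, c(3L, 2L, 1L, 0L))
  for (L in 1:12) {
    for (i in 0:(2^L - 1)) {
      g <- paste(c("A", "C")[1 + ((i %/% 2^(0:(L - 1))) %% 2)], collapse = "")
      expect_equal(build_suffix_array(g)$sa, brute_suffix_sort(g))
    }
  }
})

test_that("suffix array matches brute force on random 4-letter genomes", {
  set.seed(11)
  for (t in 1:100) {
    g <- paste(sample(c("A", "C", "G", "T"), sample(5:300, 1), TRUE),
               collapse = "")
    expect_equal(build_suffix_array(g)$sa, brute_suffix_sort(g))
  }
})

test_that("indirect spectrum view equals the direct spectrum element-wise", {
  for (t in 1:50) {
    g <- gen_genome(50 + 39 * t, repeat_fraction = (t %% 4) / 5,
                    repeat_unit = 37, seed = t)
    sa <- build_suffix_array(g)
    for (k in c(4, 8, 12)) {
      expect_identical(spectrum_values(spectrum_view(sa, k)),
                       spectrum_values(build_spectrum(g, k)))
    }
  }
  # genomes with ambiguous bases: windows dropped consistently on both paths
  g <- "ACGTNNACGTACNGTTTACGT"
  sa <- build_suffix_array(g)
  expect_identical(spectrum_values(spectrum_view(sa, 3)),
                   spectrum_values(build_spectrum(g, 3)))
})

test_that("rank and occurrence oracles match the definition", {
  S <- build_spectrum("GCCACC", 2)
  expect_equal(rank_oracle(S, encode_kmer(c("CC", "AC", "AG"))), c(2, 0, -1))
  expect_equal(occ_count(S, encode_kmer(c("CC", "AG"))), c(2, 0))
  expect_equal(occ_count(build_spectrum("AAAA", 2), 0), 3)
})

test_that("FASTA and query-file round trips work", {
  tmp <- tempfile(fileext = ".fa")
  seqs <- c(chr1 = gen_genome(500, seed = 1), chr2 = gen_genome(300, seed = 2))
  write_genome_fasta(seqs, tmp)
  back <- read_genome_fasta(tmp)
  expect_equal(unname(back), unname(seqs))
  expect_equal(names(back), names(seqs))
  qf <- tempfile(fileext = ".txt")
  writeLines(c("ACGT", "42", "TTTT"), qf)
  expect_equal(read_kmer_queries(qf, 4), c(encode_kmer("ACGT"), 42,
                                           encode_kmer("TTTT")))
})
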