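test_that("MPHF is a bijection on its keys and total on non-keys", {
  m1 <- build_mphf(42)
  expect_equal(mphf_lookup(m1, 42), 0)
  expect_true(mphf_lookup(m1, 7) %in% 0)
  set.seed(21)
  keys <- sample(0:(4^12 - 1), 10000)
  m <- build_mphf(keys)
  slots <- mphf_lookup(m, keys)
  expect_equal(sort(slots), 0:9999)          # exact image, no collisions
  nonkeys <- setdiff(sample(0:(4^12 - 1), 2000), keys)
  s2 <- mphf_lookup(m, nonkeys)
  expect_true(all(s2 >= 0 & s2 < 10000))     # arbitrary but in range
  expect_error(build_mphf(c(1, 2, 1)), "duplicate")
  expect_lte(m$bits_per_key, 8)
})

test_that("a perfectly linear list yields an all-zero error array", {
  S <- gen_sorted_list(256, 256, seed = 1)   # values 0..255, rank = value
  ex <- build_exact(S, 4)
  expect_equal(fw_access(ex$E, 0:(ex$n - 1)), rep(0, ex$n))
})

test_that("exact rank equals the oracle on the worked example and universes", {
  S <- build_spectrum("GCCACC", 2)
  ex <- build_exact(S, 1)
  q <- encode_kmer(c("AC", "CA", "CC", "GC"))
  expect_equal(exact_rank(ex, S, q), c(0, 1, 2, 4))
  expect_equal(exact_rank(ex, S, encode_kmer("CC")), 2)
  for (k in c(3, 5, 6)) {
    Sk <- gen_sorted_list(max(8, 4^k %/% 4), 4^k, dup_rate = 0.5,
                          seed = 90 + k)
    v <- spectrum_values(Sk)
    univ <- 0:(4^k - 1)
    ex <- build_exact(Sk, 3)
    expect_equal(exact_rank(ex, Sk, univ), rank_binary_oracle(v, univ))
  }
})

test_that("error entries stay in [-eps, eps] and E uses its exact bit count", {
  for (t in 1:10) {
    S <- gen_sorted_list(500 + 331 * t, 4^10, dup_rate = 0.3, seed = 600 + t)
    eps <- c(2, 8, 31)[1 + t %% 3]
    ex <- build_exact(S, eps)
    E_vals <- unzigzag(fw_access(ex$E, 0:(ex$n - 1)))
    expect_true(all(abs(E_vals) <= eps))
    expect_equal(ex$E$size_bits, ex$n * ceiling(log2(2 * eps + 1)))
  }
})

test_that("raising eps shrinks the PLA part and widens error entries", {
  g <- gen_genome(1e5, repeat_fraction = 0.3, repeat_unit = 400, seed = 13)
  S <- build_spectrum(g, 21)
  epss <- c(4, 16, 63)
  pla_bits <- e_bits_per_key <- numeric(length(epss))
  for (i in seq_along(epss)) {
    ex <- build_exact(S, epss[i])
    st <- pla_stats(ex$base)
    pla_bits[i] <- st$bits_total
    e_bits_per_key[i] <- ex$E$size_bits / ex$n
  }
  expect_true(all(diff(pla_bits) < 0))         # PLA component shrinks
  expect_true(all(diff(e_bits_per_key) > 0))   # E grows per key
})

test_that("exact index serializes and restores", {
  S <- gen_sorted_list(2000, 4^10, dup_rate = 0.4, seed = 31)
  ex <- build_exact(S, 8)
  set.seed(31)
  q <- c(sample(spectrum_values(S), 3000, TRUE),
         sample(0:(4^10 - 1), 3000, TRUE))
  back <- pla_deserialize(pla_serialize(ex))
  expect_s3_class(back, "pla_index_exact")
  expect_identical(exact_rank(back, S, q), exact_rank(ex, S, q))
  expect_error(pla_deserialize(pla_serialize(ex), expect_variant = "repeat"),
               "exact")
})
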