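test_that("Elias-Fano round-trips and meets its size bound", {
  s <- ef_encode(0, 1)
  expect_equal(ef_access(s, 0), 0)
  v <- c(2, 3, 5, 7, 11)
  s <- ef_encode(v, 16)
  expect_equal(ef_access(s, 0:4), v)
  expect_error(ef_encode(c(3, 2), 16), "non-decreasing")
  expect_error(ef_encode(c(3, 16), 16), "universe")
  set.seed(3)
  for (t in 1:20) {
    m <- sample(c(10, 500, 10000), 1)
    U <- m * sample(c(2, 17, 1000), 1)
    v <- sort(sample(0:(U - 1), m, replace = TRUE))
    s <- ef_encode(v, U)
    idx <- sample(0:(m - 1), min(m, 500))
    expect_equal(ef_access(s, idx), v[idx + 1])
    expect_lte(ef_size_bits(s), m * log2(U / m) + 2 * m + 64)
  }
  # negative values via offset (used for start values as low as -eps)
  s <- ef_encode(c(-4, -1, 0, 7), 20, offset = -4)
  expect_equal(ef_access(s, 0:3), c(-4, -1, 0, 7))
})

test_that("delta-from-uniform encoding reconstructs X exactly", {
  k <- 3
  grid <- floor((0:7) * 4^k / 8)
  s <- delta_x_encode(grid, k)
  expect_lte(s$width, 1)
  expect_equal(delta_x_access(s, 0:7), grid)
  X <- c(0, 8, 16, 21, 26, 48, 56)
  s <- delta_x_encode(X, 3)
  expect_equal(delta_x_access(s, 0:6), X)
  set.seed(4)
  for (t in 1:20) {
    m <- sample(5:2000, 1)
    k <- sample(c(8, 12, 21), 1)
    X <- sort(sample(0:min(4^k - 1, 1e7), m))
    s <- delta_x_encode(X, k)
    expect_equal(delta_x_access(s, 0:(m - 1)), X)
  }
  # clustered input: between Elias-Fano and the naive 2k-bit encoding
  X <- sort(c(sample(0:4000, 300), 4^10 - sample(1:4000, 300)))
  s <- delta_x_encode(X, 10)
  ef <- ef_encode(X, 4^10)
  expect_gte(s$size_bits, ef_size_bits(ef) * 0.9)
  expect_lte(s$size_bits, 2 * 10 * length(X))
})

test_that("zigzag transform matches 2|d| + t and inverts", {
  expect_equal(zigzag(c(0, 3, -3)), c(0, 7, 6))
  expect_equal(unzigzag(c(0, 7, 6)), c(0, 3, -3))
  d <- -50:50
  expect_equal(unzigzag(zigzag(d)), d)
})

test_that("DAC sequences round-trip and beat fixed-width on skewed data", {
  s <- dac_encode(rep(0, 100))
  expect_equal(dac_access(s, 0:99), rep(0, 100))
  set.seed(5)
  v <- floor(runif(2000)^8 * 1e6)  # heavily skewed to small values
  s <- dac_encode(v)
  expect_equal(dac_access(s, 0:1999), v)
  fixed_bits <- length(v) * ceiling(log2(max(v) + 1))
  expect_lt(s$size_bits, fixed_bits)
  expect_error(dac_encode(-1), "non-negative")
})

test_that("fixed-width packing is lossless within its width", {
  v <- sample(0:31, 200, TRUE)
  s <- fw_encode(v, 5)
  expect_equal(fw_access(s, 0:199), v)
  expect_equal(s$size_bits, 1000)
  expect_error(fw_encode(32, 5), "does not fit")
  # wide values crossing word boundaries
  v <- sample(0:(2^40), 50)
  s <- fw_encode(v, 41)
  expect_equal(fw_access(s, 0:49), v)
})
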