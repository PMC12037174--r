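test_that("prefix table brackets the worked example and degenerate cases", {
  f <- fig2_fixture()
  D <- f$index$D
  expect_equal(D$bl, 4)
  expect_equal(fw_access(D$entries, 0:4), c(0, 2, 5, 5, 7))
  # single segment: constant-zero table with sentinel
  S <- gen_sorted_list(50, 50, seed = 1)
  idx <- pla_index(S, 2)
  expect_equal(idx$b, 1)
  ent <- fw_access(idx$D$entries, 0:idx$D$bl)
  expect_equal(ent, c(rep(0, idx$D$bl), 2))
  # definition check on random X: all j < D[i] have top-bit prefix < i
  set.seed(9)
  X <- sort(sample(0:(4^8 - 1), 200))
  pt <- build_prefix_table(X, 8)
  ent <- fw_access(pt$entries, 0:pt$bl)
  tops <- floor(X / 4^8 * pt$bl)
  for (i in seq_len(pt$bl) - 1) {
    j <- ent[i + 1]
    if (j > 0) expect_true(all(tops[1:j] < i))
    if (j < length(X)) expect_gte(tops[j + 1], i)
  }
})

test_that("pla_est reproduces the worked interpolation exactly", {
  f <- fig2_fixture()
  expect_identical(pla_est(f$index, 30), 534)
  expect_equal(pla_est(f$index, 26), 494)  # at a breakpoint: the start value
  expect_equal(pla_est(f$index, 48), 710)  # next segment's start value
  expect_true(is.na(pla_est(f$index, 60)))  # beyond the last breakpoint
})

test_that("estimates honour the deployed error bound on random indexes", {
  for (t in 1:25) {
    S <- gen_sorted_list(100 + 97 * t, 4^9, dup_rate = 0.3, seed = 300 + t)
    eps <- c(1, 4, 16)[1 + t %% 3]
    for (variant in c("basic", "repeat")) {
      idx <- pla_index(S, eps, variant)
      m <- guarantee_margins(idx, S)
      expect_lte(m[1], 0)
      expect_lt(m[2], 1)
    }
  }
})

test_that("search and rank agree with oracles over full small universes", {
  for (k in 2:5) {
    S <- gen_sorted_list(max(4, 4^k %/% 3), 4^k, dup_rate = 0.4,
                         seed = 70 + k)
    v <- spectrum_values(S)
    univ <- 0:(4^k - 1)
    truth <- rank_binary_oracle(v, univ)
    for (x_encoding in c("delta", "ef")) {
      ib <- pla_index(S, 2, "basic", x_encoding)
      expect_equal(pla_rank(ib, S, univ), truth)
      sr <- pla_search(ib, S, univ)
      expect_equal(sr >= 0, truth >= 0)
      expect_true(all(v[sr[sr >= 0] + 1] == univ[sr >= 0]))
    }
    ir <- pla_index(S, 2, "repeat")
    expect_equal(pla_rank(ir, S, univ), truth)
  }
})

test_that("the bracketed breakpoint search equals the unconstrained one", {
  for (t in 1:10) {
    S <- gen_sorted_list(2000, 4^10, dup_rate = 0.2, seed = 40 + t)
    idx <- pla_index(S, 4)
    set.seed(t)
    q <- sort(sample(idx$X0:idx$Xb, 2000))
    expect_equal(plaindex:::.pla_locate_cpp(idx, q, TRUE),
                 plaindex:::.pla_locate_cpp(idx, q, FALSE))
  }
})

test_that("prefix-table brackets stay near the expected 1/ell width", {
  S <- gen_sorted_list(5000, 4^12, dup_rate = 0.2, seed = 77)
  idx <- pla_index(S, 2)
  ent <- fw_access(idx$D$entries, 0:idx$D$bl)
  brackets <- diff(ent)
  expect_lte(mean(brackets), 2 / idx$D$ell)
})

test_that("choose_eps is self-consistent, monotone and rejects tiny budgets", {
  g <- gen_genome(2e5, repeat_fraction = 0.2, repeat_unit = 500, seed = 6)
  S <- build_spectrum(g, 21)
  pilot <- pla_index(S, 256)
  st <- pla_stats(pilot)
  target <- (st$bits_total + st$overhead_bits) / 8
  e <- choose_eps(S, target)
  expect_gte(e, 128)
  expect_lte(e, 512)
  expect_lte(choose_eps(S, 2 * target), e)   # more memory never raises eps
  expect_equal(choose_eps(gen_sorted_list(50, 4^8, seed = 2), 1e6), 1)
  expect_error(choose_eps(S, 3), "minimum achievable")
})

test_that("serialization round-trips bit-exactly and rejects corruption", {
  S <- gen_sorted_list(3000, 4^10, dup_rate = 0.4, seed = 12)
  v <- spectrum_values(S)
  set.seed(12)
  q <- c(sample(v, 5000, TRUE), sample(0:(4^10 - 1), 5000, TRUE))
  for (variant in c("basic", "repeat")) {
    idx <- pla_index(S, 8, variant)
    bytes <- pla_serialize(idx)
    back <- pla_deserialize(bytes)
    expect_identical(pla_search(back, S, q), pla_search(idx, S, q))
    expect_identical(pla_rank(back, S, q), pla_rank(idx, S, q))
    # truncation is a deterministic, named error
    expect_error(pla_deserialize(bytes[1:(length(bytes) - 10)]), "truncated")
    expect_error(pla_deserialize(bytes[1:6]), "magic")
    bad <- bytes
    bad[1] <- as.raw(0)
    expect_error(pla_deserialize(bad), "magic")
  }
  # cross-variant confusion is rejected via the variant tag
  idx <- pla_index(S, 8, "repeat")
  expect_error(pla_deserialize(pla_serialize(idx), expect_variant = "basic"),
               "repeat")
  # file round trip
  p <- tempfile(fileext = ".idx")
  pla_save(idx, p)
  expect_identical(pla_search(pla_load(p), S, q), pla_search(idx, S, q))
})

test_that("queries outside the breakpoint range return not-found", {
  S <- gen_sorted_list(100, 4^8, seed = 3)
  idx <- pla_index(S, 2)
  below <- idx$X0 - 1
  above <- idx$Xb + 1
  if (below >= 0) expect_equal(pla_search(idx, S, below), -1)
  if (above < 4^8) expect_equal(pla_rank(idx, S, above), -1)
})
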