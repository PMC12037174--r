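test_that("generators are deterministic under their seeds", {
  expect_identical(gen_genome(5000, 0.5, 200, seed = 3),
                   gen_genome(5000, 0.5, 200, seed = 3))
  expect_false(gen_genome(5000, 0.5, 200, seed = 3) ==
                 gen_genome(5000, 0.5, 200, seed = 4))
  expect_identical(spectrum_values(gen_sorted_list(500, 4^8, 0.5, seed = 9)),
                   spectrum_values(gen_sorted_list(500, 4^8, 0.5, seed = 9)))
})

test_that("repeat content drives the N/n ratio of the spectrum", {
  S0 <- build_spectrum(gen_genome(1e5, 0, 500, seed = 1), 21)
  expect_lt(S0$N / S0$n, 1.01)   # random 21-mers almost never collide
  S5 <- build_spectrum(gen_genome(1e5, 0.5, 500, seed = 1), 21)
  expect_gt(S5$N / S5$n, 1.2)
})

test_that("sorted-list generator controls duplication as specified", {
  S <- gen_sorted_list(4000, 4^12, dup_rate = 0, seed = 2)
  expect_equal(S$N, S$n)
  S2 <- gen_sorted_list(4000, 4^12, dup_rate = 0.5, seed = 2)
  expect_gt(S2$N / S2$n, 1.8)    # geometric tail: mean multiplicity ~2
  expect_lt(S2$N / S2$n, 2.2)
  # outputs satisfy the sorted-list invariants
  v <- spectrum_values(S2)
  expect_false(is.unsorted(v))
  expect_equal(S2$n, length(unique(v)))
  expect_true(all(v >= 0 & v < 4^S2$k))
})

test_that("repeat stretching saves more segments on more repetitive genomes", {
  savings <- vapply(c(0.2, 0.5, 0.8), function(rf) {
    S <- build_spectrum(gen_genome(3e5, rf, 400, seed = 9), 21)
    bb <- build_segments(S, 15, "basic")$b
    br <- build_segments(S, 15, "repeat")$b
    (bb - br) / bb
  }, numeric(1))
  expect_true(all(diff(savings) > 0))
})

test_that("the worked-example fixture carries the documented values", {
  f <- fig2_fixture()
  expect_equal(f$X[5:6], c(26, 48))       # 0-based indices 4 and 5
  expect_equal(f$Ystart[5], 494)
  expect_equal(f$Yend[6], 714)
  expect_equal(f$index$eps, 4)
  expect_equal(f$index$D$bl, 4)
  expect_equal(f$est, 534)
  expect_equal(f$window, c(530, 538))
})
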