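test_that("fitter accepts collinear points and rejects impossible streams", {
  f <- fitter_new()
  expect_true(fitter_add(f, 0, 0, 0))
  expect_true(fitter_add(f, 1, 1, 1))
  expect_true(fitter_add(f, 2, 2, 2))
  ln <- fitter_extract_line(f)
  expect_equal(ln$y_first, 0)
  expect_equal(ln$y_last, 2)

  f2 <- fitter_new()
  expect_true(fitter_add(f2, 0, 0, 0))
  expect_true(fitter_add(f2, 1, 5, 5))
  expect_false(fitter_add(f2, 2, 0, 0))   # no line through (0,0),(1,5),(2,0)
  expect_equal(fitter_size(f2), 2)        # failed add leaves state unchanged
  expect_error(fitter_add(f2, 1, 0, 0), "strictly increasing")
})

test_that("fitter feasibility agrees with the pairwise LP oracle", {
  for (t in 1:200) {
    st <- random_stream(sample(3:12, 1), seed = t)
    f <- fitter_new()
    kept <- list(x = numeric(0), lo = numeric(0), hi = numeric(0))
    for (i in seq_along(st$x)) {
      trial <- list(x = c(kept$x, st$x[i]), lo = c(kept$lo, st$lo[i]),
                    hi = c(kept$hi, st$hi[i]))
      ok <- fitter_add(f, st$x[i], st$lo[i], st$hi[i])
      expect_equal(ok, lp_feasible(trial$x, trial$lo, trial$hi))
      if (ok) kept <- trial
    }
  }
})

test_that("extracted line has the minimal feasible start value", {
  f <- fitter_new()
  fitter_add(f, 0, 0, 2)
  fitter_add(f, 10, 0, 2)
  expect_equal(fitter_extract_line(f)$y_first, 0)
  # near-flat regime: the chosen start never exceeds rank(x_end) - eps
  set.seed(5)
  for (t in 1:50) {
    n <- sample(3:10, 1)
    eps <- sample(1:4, 1)
    x <- cumsum(sample(1:20, n, TRUE))
    ranks <- sort(sample(0:(2 * eps - 1), n, TRUE))  # flat: span < 2 eps
    f <- fitter_new()
    ok <- all(vapply(seq_len(n), function(i)
      fitter_add(f, x[i], ranks[i] - eps, ranks[i] + eps), logical(1)))
    expect_true(ok)  # the explicit flat-case line always fits
    expect_lte(fitter_extract_line(f)$y_first, ranks[n] - eps + 1e-9)
  }
})

test_that("perfectly linear lists need a single segment", {
  S <- gen_sorted_list(200, 200, dup_rate = 0, seed = 1)  # values 0..199
  expect_equal(spectrum_values(S), 0:199)
  for (eps in c(1, 4, 16)) {
    expect_equal(build_segments(S, eps)$b, 1)
  }
})

test_that("the worked 2-spectrum builds a valid tiny index", {
  S <- build_spectrum("GCCACC", 2)
  idx <- pla_index(S, 1)
  m <- guarantee_margins(idx, S)
  expect_lte(m[1], 0)
  expect_lt(m[2], 1)
  v <- spectrum_values(S)
  expect_equal(pla_rank(idx, S, v), rank_oracle(S, v))
})

test_that("eps must be a positive integer", {
  S <- build_spectrum("GCCACC", 2)
  expect_error(build_segments(S, 0), "positive integer")
  expect_error(build_segments(S, 1.5), "positive integer")
})

test_that("min_segments_oracle handles the canonical cases", {
  expect_equal(min_segments_oracle(c(0, 1, 2), c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(min_segments_oracle(c(0, 1, 2), c(0, 5, 0), c(0, 5, 0)), 2)
})

test_that("greedy segment counts equal the DP oracle on random lists", {
  for (t in 1:60) {
    n <- sample(10:200, 1)
    eps <- sample(c(1, 2, 4, 8), 1)
    S <- gen_sorted_list(n, 4^8, dup_rate = 0.3, seed = 1000 + t)
    d <- plaindex:::.distinct_ranks_cpp(spectrum_values(S))
    seg <- build_segments(S, eps, "basic")
    expect_equal(seg$b,
                 min_segments_oracle(d$x, d$rank - eps, d$rank + eps,
                                     "shared"))
    segr <- build_segments(S, eps, "repeat")
    expect_equal(segr$b,
                 min_segments_oracle(d$x, d$rank - eps,
                                     d$rank + eps + d$occ - 1, "partition"))
  }
})

test_that("forced breaks are rare and structural invariants hold", {
  total_b <- 0
  total_forced <- 0
  for (t in 1:30) {
    S <- gen_sorted_list(50 + 60 * t, 4^10, dup_rate = 0.25, seed = 2000 + t)
    eps <- c(2, 4, 8, 16)[1 + t %% 4]
    built <- expect_index_invariants(S, eps)
    total_b <- total_b + built$seg_basic$b + built$seg_repeat$b
    total_forced <- total_forced + built$seg_basic$forced +
      built$seg_repeat$forced
  }
  g <- gen_genome(1e5, repeat_fraction = 0.4, repeat_unit = 300, seed = 7)
  Sg <- build_spectrum(g, 21)
  for (eps in c(15, 63)) {
    built <- expect_index_invariants(Sg, eps)
    total_b <- total_b + built$seg_basic$b
    total_forced <- total_forced + built$seg_basic$forced
  }
  expect_lte(total_forced, 0.01 * total_b)
})
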