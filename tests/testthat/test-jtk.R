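d <- diel_design()
times <- d$sample_times_zt

test_that("reference rank patterns respect cosine symmetry and periodicity", {
  t24 <- seq(0, 22, by = 2)
  r0 <- reference_rank_pattern(24, 0, t24)
  expect_equal(which.max(r0), 1)             # maximum at t = 0
  expect_equal(r0[2], r0[12])                # ties at t and 24 - t
  expect_equal(r0[4], r0[10])
  expect_equal(reference_rank_pattern(24, 24, t24), r0)   # lag + period
  r12 <- reference_rank_pattern(24, 12, t24)
  expect_equal(rank(-r0), r12)               # antiphase reverses ranks
})

test_that("the S statistic counts concordant minus discordant pairs", {
  expect_equal(kendall_S(c(1, 2, 3, 4), c(1, 2, 3, 4))$S, 6)
  expect_equal(kendall_S(c(4, 3, 2, 1), c(1, 2, 3, 4))$S, -6)
  expect_equal(kendall_S(c(1, 3, 2, 4), c(1, 2, 3, 4))$S, 4)
  ks <- kendall_S(c(1, 3, 2, 4), c(1, 2, 3, 4))
  expect_equal(ks$concordant, 5)
  expect_equal(ks$discordant, 1)
  # ties in the reference contribute nothing
  expect_equal(kendall_S(c(1, 2, 3), c(1, 1, 2))$S, 2)
  expect_error(kendall_S(1:4, 1:3), "length")
  expect_error(kendall_S(1:2, 1:2), "3 points")
  # agreement with an independently written loop, random cases
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(10)
    r <- rank(sample(1:5, 10, replace = TRUE), ties.method = "average")
    expect_equal(kendall_S(x, r)$S, s_stat_oracle(x, r))
  }
})

test_that("the exact null enumerates correctly for distinct ranks at n = 3", {
  nd <- exact_null_distribution(c(1, 2, 3))
  expect_equal(nd$S, c(-3, -1, 1, 3))
  expect_equal(nd$prob, c(1, 2, 2, 1) / 6)
})

test_that("the exact null is a symmetric probability distribution", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:14, 1)
    ref <- rank(sample(1:5, n, replace = TRUE), ties.method = "average")
    nd <- exact_null_distribution(ref)
    expect_equal(sum(nd$prob), 1, tolerance = 1e-12)
    expect_equal(nd$prob, rev(nd$prob), tolerance = 1e-12)
    expect_equal(range(nd$S), c(-nd$max_S, nd$max_S))
  }
  expect_error(exact_null_distribution(rank(rnorm(30))), "limit")
})

test_that("the DP null equals the exhaustive permutation null (small n)", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    ref <- rank(sample(1:4, n, replace = TRUE), ties.method = "average")
    x <- rnorm(n)
    null <- exact_null_distribution(ref)
    s_obs <- kendall_S(x, ref)$S
    p_dp <- sum(null$prob[null$S >= s_obs - 1e-9])
    expect_equal(p_dp, permutation_oracle_p(x, ref), tolerance = 1e-12)
  }
  # perfect concordance against 4 distinct ranks: 1 of 24 permutations
  expect_equal(permutation_oracle_p(c(10, 20, 30, 40), c(1, 2, 3, 4)), 1 / 24)
  expect_error(permutation_oracle_p(rnorm(9), 1:9), "n <= 8")
})

test_that("jtk_test recovers phase of noise-free cosines and their negations", {
  s <- simulate_series(d, amplitude = 1, phase_zt = 4, noise_sd = 0)
  r <- jtk_test(s, times)
  expect_equal(r$phase_zt, 4)
  expect_equal(r$best_period_h, 24)
  expect_equal(r$tau, 1)
  expect_equal(r$n_combinations, 12)
  expect_equal(r$p_adjusted, min(1, r$p_exact * 12))
  expect_equal(r$amplitude_est, 1, tolerance = 0.05)
  rn <- jtk_test(-s, times)
  expect_equal((rn$phase_zt - r$phase_zt) %% 24, 12)
})

test_that("circularly shifting a series shifts the reported phase equally", {
  base <- simulate_series(d, amplitude = 1, phase_zt = 2, noise_sd = 0)
  p0 <- jtk_test(base, times)$phase_zt
  for (k in c(1, 3, 6)) {
    shifted <- simulate_series(d, amplitude = 1, phase_zt = 2 + 2 * k,
                               noise_sd = 0)
    pk <- jtk_test(shifted, times)$phase_zt
    expect_equal((pk - p0) %% 24, (2 * k) %% 24)
  }
})

test_that("constant series are flagged as non-rhythmic with p = 1", {
  r <- jtk_test(rep(3, 14), times)
  expect_true(r$degenerate)
  expect_equal(r$p_exact, 1)
  expect_equal(r$p_adjusted, 1)
  expect_equal(r$tau, 0)
})

test_that("detection power increases with the amplitude/noise ratio", {
  set.seed(4)
  rate <- vapply(c(0.25, 1, 4), function(snr) {
    hits <- replicate(40, {
      s <- simulate_series(d, amplitude = snr, phase_zt = sample(0:23, 1),
                           noise_sd = 1)
      jtk_test(s, times)$p_adjusted < 0.05
    })
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.5)
  expect_gt(rate[3], 0.9)
})

test_that("batch testing returns one row per series", {
  set.seed(5)
  m <- rbind(a = simulate_series(d, amplitude = 2, phase_zt = 8, noise_sd = 0.1),
             b = rnorm(14))
  res <- jtk_batch(m, times)
  expect_equal(res$series_id, c("a", "b"))
  expect_lt(res$p_adjusted[1], 0.05)
  expect_equal(res$phase_zt[1], 8)
})
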