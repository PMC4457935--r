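test_that("stage-decomposition simulator matches the literal draw process", {
  d_fast <- simulate_completion_draws(3, 4000, seed = 5)
  d_slow <- simulate_completion_draws_naive(3, 4000, seed = 6)
  expect_true(all(d_fast$draws >= 3))
  expect_true(all(d_slow >= 3))
  # same distribution: compare means (exact mean 3 * H_3 = 5.5) and a KS test
  expect_equal(mean(d_fast$draws), 5.5, tolerance = 0.1)
  expect_equal(mean(d_slow), 5.5, tolerance = 0.1)
  ks <- suppressWarnings(ks.test(d_fast$draws, d_slow))
  expect_gt(ks$p.value, 0.01)
})

test_that("completion draws hit coupon-collector expectations", {
  expect_true(all(simulate_completion_draws(1, 50, seed = 1)$draws == 1))

  d2 <- simulate_completion_draws(2, 20000, seed = 2)
  se2 <- sd(d2$draws) / sqrt(d2$n_trials)
  expect_lt(abs(mean(d2$draws) - 3), 3 * se2 + 1e-9)

  d531 <- simulate_completion_draws(531, 5000, seed = 3)
  expect_531 <- 531 * sum(1 / (1:531))
  se531 <- sd(d531$draws) / sqrt(d531$n_trials)
  expect_lt(abs(mean(d531$draws) - expect_531), 3 * se531)
  expect_error(simulate_completion_draws(0, 10, seed = 1), ">= 1")
})

test_that("exact completion CDF agrees with enumeration and Markov power", {
  expect_equal(exact_completion_cdf(2, 2), 0.5)
  expect_equal(exact_completion_cdf(2, 3), 0.75)
  # pigeonhole
  for (m in c(2, 5, 100)) expect_equal(exact_completion_cdf(m, m - 1), 0)

  for (m in 2:3) {
    for (n in m:8) {
      expect_equal(exact_completion_cdf(m, n),
                   brute_force_completion_cdf(m, n), tolerance = 1e-12,
                   label = sprintf("enumeration m=%d n=%d", m, n))
    }
  }
  for (m in 4:5) {
    for (n in m:12) {
      expect_equal(exact_completion_cdf(m, n), markov_completion_cdf(m, n),
                   tolerance = 1e-12,
                   label = sprintf("markov m=%d n=%d", m, n))
    }
  }
})

test_that("exact CDF is monotone in draws, antitone in types, with limits", {
  n <- seq(531, 8000, by = 250)
  p <- exact_completion_cdf(531, n)
  expect_true(all(diff(p) >= 0))
  strict <- n >= 2000 & n <= 6000   # strictly increasing away from the tails
  expect_true(all(diff(p[strict]) > 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(exact_completion_cdf(531, 2e4), 1 - 1e-6)
  expect_lt(exact_completion_cdf(600, 4000), exact_completion_cdf(500, 4000))
})

test_that("Monte Carlo empirical CDF tracks the exact CDF", {
  d <- simulate_completion_draws(50, 20000, seed = 8)
  for (n in c(150, 200, 300, 450)) {
    p_exact <- exact_completion_cdf(50, n)
    p_emp <- mean(d$draws <= n)
    tol <- 3 * sqrt(p_exact * (1 - p_exact) / d$n_trials)
    expect_lt(abs(p_emp - p_exact), tol + 1e-9,
              label = sprintf("empirical vs exact CDF at n=%d", n))
  }
})

test_that("confidence thresholds invert the CDF and match the Gumbel limit", {
  expect_equal(confidence_threshold(1, 0.9, method = "exact"), 1L)
  q <- confidence_threshold(531, 0.90, method = "exact")
  expect_gte(exact_completion_cdf(531, q), 0.90)
  expect_lt(exact_completion_cdf(531, q - 1), 0.90)
  expect_lt(abs(gumbel_threshold(531, 0.90) - q) / q, 0.005)
  expect_lt(abs(gumbel_threshold(531, 0.95) -
                  confidence_threshold(531, 0.95, method = "exact")) /
              confidence_threshold(531, 0.95, method = "exact"), 0.005)
  expect_error(confidence_threshold(10, 1.2), "level")
  expect_error(confidence_threshold(10, 0.9, "monte_carlo"), "seed")

  # monte carlo agrees with exact at modest problem sizes
  mc <- confidence_threshold(50, 0.9, method = "monte_carlo",
                             n_trials = 50000, seed = 12)
  expect_lt(abs(mc - confidence_threshold(50, 0.9, method = "exact")), 6)
})

test_that("coverage report flags confidence levels for a library size", {
  expect_equal(coverage_report(531, 0)$probability, 0)
  r <- coverage_report(531, 4565)
  expect_gte(r$probability, 0.90)
  expect_true(r$meets[["level_0.9"]])
  r2 <- coverage_report(5, 10)
  expect_equal(r2$probability, exact_completion_cdf(5, 10))
})

test_that("single-mutant bookkeeping and its edge cases", {
  expect_identical(single_mutant_colonies(27500, 0.166), 4565L)
  expect_identical(single_mutant_colonies(0, 0.5), 0L)
  expect_error(single_mutant_colonies(100, 1.5), "single_fraction")
})
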