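test_that("breeding success is the fledgling/nest ratio with guards", {
  expect_equal(breeding_success(50, 52), 1.04)
  expect_equal(breeding_success(40, 0), 0)
  expect_equal(breeding_success(10, 19), 1.9)
  expect_error(breeding_success(0, 5), "nests")
  expect_error(breeding_success(10, -1), "non-negative")
})

test_that("summary t test reproduces the colony comparison", {
  out <- summary_t_test(0.69, 0.10, 14, 1.04, 0.14, 14)
  # from the printed (rounded) means/SEs, t = 2.0343; the published 2.04
  # is consistent within the rounding of its inputs
  expect_lt(abs(out$t - 2.04), 0.01)
  expect_equal(out$df, 26L)
  expect_lt(abs(out$p - 0.05), 0.005)
  expect_equal(summary_t_test(1, 0.1, 5, 1, 0.2, 5)$t, 0)
  # doubling both SEs halves t
  a <- summary_t_test(0.5, 0.1, 10, 1.0, 0.2, 10)
  b <- summary_t_test(0.5, 0.2, 10, 1.0, 0.4, 10)
  expect_equal(a$t, 2 * b$t)
})

test_that("annual lambda uses consecutive-year pairs only", {
  cs <- census_series(c(2000, 2001), c(100, 110))
  expect_equal(annual_lambda(cs), c(`2000` = 1.1))
  flat <- census_series(2000:2004, rep(50, 5))
  expect_true(all(annual_lambda(flat) == 1))
  gap <- census_series(c(2000, 2002), c(100, 121))
  expect_length(annual_lambda(gap), 0L)
})

test_that("Dennis regression is exact on noise-free series", {
  yrs <- 2000:2010
  cs <- census_series(yrs, 100 * 1.05^(0:10))
  est <- dennis_stochastic_lambda(cs)
  expect_equal(est$lambda_s, 1.05, tolerance = 1e-12)
  expect_equal(est$sigma2_hat, 0, tolerance = 1e-12)
  expect_equal(est$ci, c(1.05, 1.05), tolerance = 1e-10)
  # gapped noise-free series: unequal intervals handled exactly
  keep <- c(1, 2, 3, 6, 7, 9, 11)
  cs2 <- census_series(yrs[keep], (100 * 1.1^(0:10))[keep])
  est2 <- dennis_stochastic_lambda(cs2)
  expect_equal(est2$lambda_s, 1.1, tolerance = 1e-10)
  expect_equal(est2$q, length(keep) - 1L)
  # equal to the per-step log-growth mean when intervals are all 1 year
  set.seed(12)
  counts <- exp(cumsum(c(log(200), rnorm(9, 0.03, 0.2))))
  cs3 <- census_series(2000:2009, counts)
  est3 <- dennis_stochastic_lambda(cs3)
  expect_equal(est3$mu_hat, mean(diff(log(counts))), tolerance = 1e-12)
  expect_error(dennis_stochastic_lambda(census_series(1:2, c(10, 11))),
               "at least 3")
})

test_that("Dennis estimator is unbiased with near-nominal coverage", {
  mu <- 0.05; sigma <- 0.1
  n_rep <- 200L
  lam <- numeric(n_rep); cover <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cs <- simulate_census(500, mu, sigma, years = 20,
                          seed = replicate_seeds(1234, n_rep)[i])
    est <- dennis_stochastic_lambda(cs)
    lam[i] <- est$lambda_s
    cover[i] <- est$ci[1] <= exp(mu) && exp(mu) <= est$ci[2]
  }
  expect_equal(mean(lam), exp(mu), tolerance = 0.01)
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 0.99)
})

test_that("geometric mean growth", {
  expect_equal(geometric_mean_lambda(c(1.2, 0.8)), sqrt(1.2 * 0.8),
               tolerance = 1e-12)
  expect_equal(round(geometric_mean_lambda(c(1.2, 0.8)), 4), 0.9798)
  expect_equal(geometric_mean_lambda(rep(1, 5)), 1)
  set.seed(3)
  x <- runif(10, 0.5, 1.5)
  expect_equal(geometric_mean_lambda(x), exp(mean(log(x))))
  expect_error(geometric_mean_lambda(c(1, 0)), "positive")
})

test_that("regional sums treat incomplete years as gaps by default", {
  a <- census_series(2000:2003, c(10, 20, 30, 40), "A")
  b <- census_series(c(2000, 2001, 2003), c(1, 2, 4), "B")
  wm <- sum_census(list(a, b), "WM")
  expect_equal(wm$years, c(2000L, 2001L, 2003L))
  expect_equal(wm$counts, c(11, 22, 44))
  wm2 <- sum_census(list(a, b), "WM", require_all = FALSE)
  expect_equal(wm2$counts, c(11, 22, 30, 44))
})

test_that("decline flag reports the CI position, not a point call", {
  cs <- simulate_census(500, -0.02, 0.15, years = 15, seed = 9)
  est <- dennis_stochastic_lambda(cs)
  expect_type(est$decline_flag, "logical")
  expect_equal(est$decline_flag, est$ci[1] < 1)
})
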