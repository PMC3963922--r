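test_that("stage matrix places rates per the pre-breeding census layout", {
  vr <- vital_rates(fecundity = 2, phi_first_year = 1, phi_adult = 1,
                    recruitment = c(`2` = 1), sex_ratio = 0.5)
  A <- build_stage_matrix(vr)
  expect_equal(dim(A), c(2L, 2L))
  expect_equal(unclass(A)[1, ], c(age1 = 0, breeder = 1))
  expect_equal(unclass(A)[2, ], c(age1 = 1, breeder = 1))
  # eigen oracle: with breeders surviving (phi_ad = 1) this life cycle
  # grows at the golden ratio, not at replacement
  expect_equal(asymptotic_lambda(A), (1 + sqrt(5)) / 2, tolerance = 1e-10)
  # no survival, no growth
  vr0 <- vital_rates(2, 0, 0, recruitment = c(`2` = 1))
  expect_equal(asymptotic_lambda(build_stage_matrix(vr0)), 0)
})

test_that("delayed recruitment builds the right transitions", {
  vr <- vital_rates(1.2, 0.5, 0.8,
                    recruitment = c(`2` = 0.2, `3` = 0.6, `4` = 1),
                    sex_ratio = 0.5)
  A <- unclass(build_stage_matrix(vr))
  expect_equal(dim(A), c(4L, 4L))       # age1, age2, age3, breeder
  expect_equal(A[4, 1], 0.8 * 0.2)      # recruit at age 2
  expect_equal(A[2, 1], 0.8 * 0.8)      # stay pre-breeder
  expect_equal(A[4, 3], 0.8 * 1)        # certain recruitment at age 4
  expect_equal(A[4, 4], 0.8)            # breeder survival
  expect_equal(A[1, 4], 0.5 * 1.2 * 0.5)  # sex_ratio * f * phi_1
  expect_equal(sum(A), 0.8 * 0.2 + 0.8 * 0.8 + 0.8 * 0.4 + 0.8 * 0.6 +
                 0.8 + 0.8 + 0.3)
})

test_that("asymptotic lambda matches the power-iteration oracle", {
  expect_equal(asymptotic_lambda(matrix(c(0, 0.5, 2, 0), 2)), 1)
  expect_equal(asymptotic_lambda(diag(c(1, 0.5))), 1)
  set.seed(31)
  for (i in 1:10) {
    A <- matrix(runif(16, 0, 2), 4)
    expect_equal(asymptotic_lambda(A), power_iteration_lambda(A),
                 tolerance = 1e-8)
  }
})

test_that("lambda is monotone in every matrix entry", {
  set.seed(99)
  for (i in 1:50) {
    A <- matrix(runif(9, 0, 1.5), 3)
    lam <- asymptotic_lambda(A)
    j <- sample(9, 1)
    B <- A; B[j] <- B[j] + runif(1, 0, 0.5)
    expect_gte(asymptotic_lambda(B), lam - 1e-12)
  }
})

test_that("projection iterates matrices and reports geometric growth", {
  vr <- vital_rates(1.5, 0.7, 0.85)
  A <- build_stage_matrix(vr)
  lam <- asymptotic_lambda(A)
  # from the dominant eigenvector, growth equals lambda immediately
  v <- Re(eigen(unclass(A))$vectors[, 1]); v <- v / sum(v)
  out <- project(unclass(A), v, years = 10)
  expect_equal(out$geometric_mean_growth, lam, tolerance = 1e-10)
  # alternating matrices on a common eigenvector
  M1 <- diag(c(1.2, 1.2)); M2 <- diag(c(0.8, 0.8))
  out2 <- project(list(M1, M2, M1, M2), c(1, 1))
  expect_equal(out2$geometric_mean_growth, sqrt(1.2 * 0.8),
               tolerance = 1e-12)
  # zero start stays zero
  out3 <- project(unclass(A), c(0, 0, 0, 0, 0), years = 3)
  expect_true(all(out3$trajectory == 0))
  expect_error(project(unclass(A), c(1, 1), years = 2), "dimensions")
})

test_that("lambda bounds for typical gull rates", {
  # lambda must lie between adult survival and adult survival plus the
  # fertility term, for any recruitment schedule ending by age 5
  set.seed(17)
  for (i in 1:20) {
    ages <- 2:sample(3:5, 1)
    rec <- sort(runif(length(ages)))
    rec[length(rec)] <- 1
    names(rec) <- ages
    vr <- vital_rates(1.04, 0.78, 0.83, recruitment = rec)
    lam <- asymptotic_lambda(build_stage_matrix(vr))
    expect_gte(lam, 0.83 - 1e-9)
    expect_lte(lam, 0.83 + 0.5 * 1.04 * 0.78 + 1e-9)
  }
})

test_that("immigration correction scales by marked fraction and resight", {
  est <- estimate_immigrants(2, 0.52, 0.5, 500)
  expect_equal(est$corrected, 2 / (0.52 * 0.5), tolerance = 1e-12)
  expect_equal(round(est$corrected, 2), 7.69)
  expect_equal(est$proportion_of_breeders, est$corrected / 500)
  expect_equal(estimate_immigrants(3, 1, 1, 100)$corrected, 3)
  z <- estimate_immigrants(0, 0.7, 0.5, 100)
  expect_equal(z$corrected, 0)
  expect_equal(z$proportion_of_breeders, 0)
  expect_error(estimate_immigrants(2, 0, 0.5, 100), "m_r")
  # corrected count never below the observed count
  expect_gte(est$corrected, est$observed)
})
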