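test_that("fit with p fixed at 1 recovers closed-form proportions", {
  # 100 released; 60 seen at occ 2; 30 of those at occ 3
  set <- hist_set(c(rep("111", 30), rep("110", 30), rep("100", 40)))
  ma <- build_marray(set)
  fit <- fit_cjs(ma, cjs_model_spec("t", "t"), p_fixed = 1, n_starts = 2)
  expect_true(fit$converged)
  phi <- fit$real[fit$real$parameter == "phi", ]
  expect_equal(phi$estimate[phi$occasion == 1], 0.60, tolerance = 1e-4)
  expect_equal(phi$estimate[phi$occasion == 2], 0.50, tolerance = 1e-4)
})

test_that("fitted optimum matches a brute-force grid search", {
  set <- local({
    cfg <- simulation_config(2000:2002, c(`2000` = 30),
                             survival = 0.7, resight = 0.6, seed = 21)
    simulate_histories(cfg)
  })
  ma <- build_marray(set)
  fit <- fit_cjs(ma, cjs_model_spec("a(1)", "a(1)"), n_starts = 3)
  # independent grid oracle on (phi, p) at 10^-3 resolution, using the
  # closed-form 3-occasion m-array deviance
  g <- expand.grid(phi = seq(0.001, 0.999, 1e-3),
                   p = seq(0.001, 0.999, 1e-3))
  meta <- ma$meta; m <- ma$m
  r1 <- which(meta$occasion == 1); r2 <- which(meta$occasion == 2)
  m12 <- m[r1, 2]; m13 <- m[r1, 3]; nv1 <- meta$never[r1]
  m23 <- if (length(r2)) m[r2, 3] else 0
  nv2 <- if (length(r2)) meta$never[r2] else 0
  dev <- with(g, {
    pi12 <- phi * p
    pi13 <- phi * (1 - p) * phi * p
    pi23 <- phi * p
    -2 * (m12 * log(pi12) + m13 * log(pi13) +
            nv1 * log(1 - pi12 - pi13) +
            m23 * log(pi23) + nv2 * log(1 - pi23))
  })
  best <- which.min(dev)
  expect_lte(fit$deviance, dev[best] + 1e-6)
  expect_equal(fit$real$estimate[fit$real$parameter == "phi"][1],
               g$phi[best], tolerance = 2e-3)
  expect_equal(fit$real$estimate[fit$real$parameter == "p"][1],
               g$p[best], tolerance = 2e-3)
})

test_that("nested models keep deviance monotone", {
  set <- simulate_histories(simulation_config(
    2000:2006, rep(80, 6), survival = list(first_year = 0.5, adult = 0.8),
    resight = 0.5, seed = 5))
  ma <- build_marray(set)
  fits <- lapply(c("a(1)", "a(1,>=2)", "a(1,>=2)+t", "a(1,>=2).t"),
                 function(s) fit_cjs(ma, cjs_model_spec(s, "t"),
                                     n_starts = 3, hessian = FALSE))
  devs <- vapply(fits, `[[`, 0, "deviance")
  expect_true(all(diff(devs) <= 1e-4))
})

test_that("AICc arithmetic is exact", {
  expect_equal(round(compute_aicc(4026.82, 33, 2455), 2), 4093.75)
  expect_equal(compute_aicc(11008.13, 27, 5042), 11062.43,
               tolerance = 0.005)
  expect_equal(compute_aicc(100, 0, 50), 100)
  expect_error(compute_aicc(100, 50, 51), "n_eff")
})

test_that("estimable-parameter count captures CJS confounding", {
  # fully time-dependent single-age CJS: 2(T-1) - 1 estimable
  set <- simulate_histories(simulation_config(
    2000:2004, rep(150, 4), survival = 0.75, resight = 0.6, seed = 9))
  ma <- build_marray(set)
  fit <- fit_cjs(ma, cjs_model_spec("t", "t"), n_starts = 3)
  T <- length(set$occasions)
  expect_equal(fit$np_nominal, 2 * (T - 1))
  expect_equal(fit$np, 2 * (T - 1) - 1)
  # constant phi, constant p: both estimable
  fit2 <- fit_cjs(ma, cjs_model_spec("a(1)", "a(1)"), n_starts = 2)
  expect_equal(fit2$np, 2L)
  # well-conditioned covariate model: rank equals nominal
  fish <- covariate_series("FISH", 2000:2004, c(0.3, -1.2, 0.8, 1.7, -0.4))
  fit3 <- fit_cjs(ma, cjs_model_spec("a(1)+FISH", "a(1)"),
                  covariates = list(FISH = fish), n_starts = 2)
  expect_equal(fit3$np, fit3$np_nominal)
})

test_that("model selection table sorts, differences and breaks ties", {
  tab <- data.frame(model = c("12EB", "13EB"), np = c(33L, 40L),
                    deviance = c(4026.82, 4008.18),
                    aicc = c(4093.75, 4089.55))
  out <- model_selection_table(tab)
  expect_equal(out$model, c("13EB", "12EB"))
  expect_equal(out$delta_aicc, c(0, 4.20), tolerance = 1e-9)
  # permutation invariance
  out2 <- model_selection_table(tab[2:1, ])
  expect_equal(out2$model, out$model)
  # ties break toward fewer parameters
  tie <- data.frame(model = c("big", "small"), np = c(10L, 3L),
                    deviance = c(1, 2), aicc = c(50, 50))
  expect_equal(model_selection_table(tie)$model[1], "small")
})

test_that("confidence intervals live in (0,1) and cover the truth", {
  phi_true <- 0.75
  hits <- 0L; n_rep <- 40L
  for (seed in replicate_seeds(77, n_rep)) {
    set <- simulate_histories(simulation_config(
      2000:2004, rep(60, 4), survival = phi_true, resight = 0.6,
      seed = seed))
    fit <- fit_cjs(build_marray(set), cjs_model_spec("a(1)", "a(1)"),
                   n_starts = 1)
    phi <- fit$real[fit$real$parameter == "phi", ][1, ]
    expect_true(phi$lcl > 0 && phi$ucl < 1)
    if (phi$lcl <= phi_true && phi_true <= phi$ucl) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)   # coarse coverage check
})
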