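test_that("Pearson component arithmetic on 2x2 tables", {
  perfect <- gulldemog:::gof_chisq(matrix(c(10, 10, 10, 10), 2),
                                   "TEST3.SR", "g", 2000)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$df, 1L)
  diag40 <- gulldemog:::gof_chisq(matrix(c(20, 0, 0, 20), 2),
                                  "TEST3.SR", "g", 2000)
  expect_equal(diag40$chi2, 40)
  expect_equal(diag40$df, 1L)
})

test_that("pooling merges low-expectation cells and flags degeneracy", {
  # a 2x4 with two thin columns pools to fewer columns, df shrinks
  tab <- matrix(c(20, 18, 1, 0, 0, 1, 15, 16), 2)
  pooled <- gulldemog:::pool_table(tab)
  expect_true(all(outer(rowSums(pooled), colSums(pooled)) /
                    sum(pooled) >= 2))
  expect_lt(ncol(pooled), 4L)
  # tiny 2x2 cannot be pooled further: degenerate
  tiny <- gulldemog:::gof_chisq(matrix(c(1, 0, 0, 1), 2),
                                "TEST2.CT", "g", 2000)
  expect_true(tiny$degenerate)
  expect_equal(tiny$df, 0L)
})

test_that("single-cohort data degenerate all TEST3.SR tables", {
  set <- simulate_histories(simulation_config(
    2000:2005, c(`2000` = 200), survival = 0.8, resight = 0.6, seed = 3))
  comps <- gof_components(set)
  sr <- Filter(function(c) c$name == "TEST3.SR", comps)
  expect_true(all(vapply(sr, `[[`, TRUE, "degenerate")))
})

test_that("global test sums non-degenerate components", {
  mk <- function(chi2, df, degen = FALSE)
    structure(list(name = "TEST2.CT", group = "g", occasion = 1,
                   chi2 = chi2, df = df, degenerate = degen,
                   table = NULL), class = "gof_component")
  g <- gof_global(list(mk(3, 2), mk(5, 4), mk(99, 9, degen = TRUE)))
  expect_equal(g$chi2, 8)
  expect_equal(g$df, 6L)
  expect_equal(g$p, pchisq(8, 6, lower.tail = FALSE))
  expect_error(gof_global(list()), "empty")
  expect_warning(gof_global(list(mk(1, 1, TRUE))), "degenerate")
})

test_that("type-I error is roughly calibrated on CJS-true data", {
  # quick version of the full calibration (which runs in acceptance):
  # 120 replicates, moderate scale
  # CJS-true world: no age structure in survival or resighting
  rej <- 0L; n_rep <- 120L
  for (seed in replicate_seeds(42, n_rep)) {
    set <- simulate_histories(simulation_config(
      2000:2007, rep(70, 7), survival = 0.72, resight = 0.55,
      seed = seed))
    g <- gof_cjs(set)
    if (!is.na(g$p) && g$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / n_rep, 0.12)
})

test_that("cohort-wise components absorb modeled age structure", {
  # age-structured survival violates the age-free CJS on pooled data
  # (transience signal) but is invisible within cohorts, where the
  # age-structured general model is the right null
  pooled_p <- numeric(20); cohort_p <- numeric(20)
  for (i in seq_along(pooled_p)) {
    set <- simulate_histories(simulation_config(
      2000:2007, rep(150, 7),
      survival = list(first_year = 0.35, adult = 0.8),
      resight = 0.55, seed = replicate_seeds(3, 20)[i]))
    pooled_p[i] <- gof_cjs(set)$p
    cohort_p[i] <- gof_cjs(set, by_cohort = TRUE)$p
  }
  expect_gt(mean(pooled_p < 0.05), 0.8)   # pooled test flags the age effect
  expect_lt(mean(cohort_p < 0.05), 0.3)   # cohort-wise test does not
})

test_that("transient-rich data inflate TEST3.SR", {
  med_sr <- function(first_year_phi) {
    stats <- vapply(replicate_seeds(7, 30), function(seed) {
      set <- simulate_histories(simulation_config(
        2000:2007, rep(120, 7),
        survival = list(first_year = first_year_phi, adult = 0.8),
        resight = 0.6, seed = seed))
      comps <- Filter(function(c) c$name == "TEST3.SR" && !c$degenerate,
                      gof_components(set))
      sum(vapply(comps, `[[`, 0, "chi2"))
    }, 0)
    stats::median(stats)
  }
  # strong transience: first-interval survival far below adult survival
  expect_gt(med_sr(0.25), med_sr(0.8))
})
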