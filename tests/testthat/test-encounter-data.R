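test_that("inp dialect parses, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("1100 1;", "1010 1;", "1000 1;"), f)
  set <- read_histories(f, "inp", occasions = 1998:2001)
  expect_equal(nrow(set$detections), 3L)
  expect_equal(unname(set$detections[1, ]), c(1L, 1L, 0L, 0L))
  expect_equal(set$occasions, 1998:2001)

  # group counts expand records and label groups
  f2 <- withr::local_tempfile(fileext = ".inp")
  writeLines("1100 2 1;", f2)
  set2 <- read_histories(f2, "inp", occasions = 1998:2001,
                         groups = c("EB", "DO"))
  expect_equal(table(set2$group), table(c("EB", "EB", "DO")))

  # tabular round trip preserves structure
  ft <- withr::local_tempfile(fileext = ".csv")
  write_histories(set, ft, "tabular")
  back <- read_histories(ft, "tabular")
  expect_equal(unname(back$detections), unname(set$detections))
  expect_equal(back$occasions, set$occasions)
  expect_equal(back$group, set$group)

  # inp round trip
  fi <- withr::local_tempfile(fileext = ".inp")
  write_histories(set2, fi, "inp")
  back2 <- read_histories(fi, "inp", occasions = 1998:2001,
                          groups = unique(set2$group))
  expect_equal(sort(back2$group), sort(set2$group))
  expect_equal(colSums(back2$detections), colSums(set2$detections))
})

test_that("malformed inp records raise errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("1100 1;", "1020 1;"), f)
  expect_error(read_histories(f, "inp", occasions = 1998:2001),
               "line 2.*illegal symbol")
  writeLines(c("110 1;"), f)
  expect_error(read_histories(f, "inp", occasions = 1998:2001),
               "length 3 != 4")
  writeLines(c("1100 1"), f)
  expect_error(read_histories(f, "inp", occasions = 1998:2001),
               "missing terminating")
  writeLines(c("0000 1;"), f)
  expect_error(read_histories(f, "inp", occasions = 1998:2001),
               "no detections")
})

test_that("m-array matches hand enumeration and re-release convention", {
  set <- hist_set(c("101", "110", "100"))
  ma <- build_marray(set)
  r1 <- ma$meta[ma$meta$occasion == 1L, ]
  expect_equal(r1$R, 3L)
  expect_equal(unname(ma$m[ma$meta$occasion == 1L, ]), c(0L, 1L, 1L))
  expect_equal(r1$never, 1L)
  # only "110" is re-released at occasion 2 (standard CJS re-release rule)
  r2 <- ma$meta[ma$meta$occasion == 2L, ]
  expect_equal(r2$R, 1L)
  expect_equal(r2$never, 1L)
  expect_equal(sum(ma$m[ma$meta$occasion == 2L, ]), 0L)
  # final-occasion release of "101" carries no multinomial cells
  r3 <- ma$meta[ma$meta$occasion == 3L, ]
  expect_equal(r3$R, 1L)
})

test_that("never-reencountered histories fill the never column", {
  set <- hist_set(c("1000", "1000", "0100"))
  ma <- build_marray(set)
  expect_true(all(ma$m == 0L))
  expect_equal(ma$meta$never, ma$meta$R)
})

test_that("m-array conservation holds on random instances and is
           permutation invariant", {
  for (seed in 1:8) {
    set <- random_small_instance(seed)
    ma <- build_marray(set)
    T <- length(ma$occasions)
    inner <- ma$meta$occasion < T
    expect_equal(ma$meta$R[inner],
                 rowSums(ma$m[inner, , drop = FALSE]) + ma$meta$never[inner])
    # permuting individuals leaves the m-array unchanged
    perm <- local({set.seed(seed + 99); sample(nrow(set$detections))})
    set2 <- capture_histories(set$detections[perm, , drop = FALSE],
                              set$occasions, group = set$group[perm])
    ma2 <- build_marray(set2)
    expect_equal(ma2$meta, ma$meta)
    expect_equal(ma2$m, ma$m)
  }
})

test_that("summaries count individuals/observations and add over merges", {
  s1 <- hist_set(c("10", "11"))
  expect_equal(summary(s1)$n_individuals, 2L)
  expect_equal(summary(s1)$n_observations, 3L)

  s2 <- hist_set(c("01", "11"), group = "other")
  merged <- merge_histories(s1, s2)
  sm <- summary(merged)
  expect_equal(sm$n_individuals,
               summary(s1)$n_individuals + summary(s2)$n_individuals)
  expect_equal(sm$n_observations,
               summary(s1)$n_observations + summary(s2)$n_observations)
})

test_that("constructor rejects invalid inputs", {
  expect_error(capture_histories(matrix(c(1, 2), 1), 2000:2001), "0/1")
  expect_error(capture_histories(matrix(0L, 1, 2), 2000:2001),
               "at least one detection")
  expect_error(capture_histories(matrix(1L, 1, 2), c(2001, 2000)),
               "strictly increasing")
})
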