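test_that("CSV read-back reproduces a written cohort exactly", {
  co <- simulate_cohort(gusto_spec(n = 60, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, "outcome")
  expect_identical(back$outcome, co$outcome)
  expect_identical(back$predictors, co$predictors)
  expect_identical(back$predictor_kinds, co$predictor_kinds)
  expect_true(file.exists(paste0(path, ".meta.json")))
  # and a second round trip is a fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("loading validates structure and rejects bad data loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,a,b", "0,1.5,0", "1,2.5,1", "0,0.5,0", "1,1.0,1"), path)
  co <- read_cohort(path, "y")
  expect_identical(dim(co), c(4L, 2L))
  expect_identical(unname(co$predictor_kinds), c("continuous", "binary"))

  expect_error(read_cohort(path, "day30"), "not present.*day30")
  expect_error(read_cohort(path, "y", c("a", "zz")), "zz")

  writeLines(c("y,a", "1,0.1", "2,0.2"), path)
  expect_error(read_cohort(path, "y"), "0/1.*2")

  writeLines(c("y,a", "1,0.1", "0,NA", "1,0.3"), path)
  expect_error(read_cohort(path, "y"), "row")
})

test_that("cohort constructor enforces its invariants", {
  expect_error(cohort(c(0, 1, 2), cbind(x = 1:3)), "0 and 1")
  expect_error(cohort(c(0, 1), cbind(x = c(1, NA))), "missing")
  expect_error(cohort(c(0, 1), cbind(x = 1:3)), "rows")
  expect_error(cohort(c(0, 1), matrix(1:2, 2)), "column names")
  expect_error(cohort(c(0, 1), cbind(x = 1:2), ids = c(1, 1)), "unique")
})

test_that("subsampling is deterministic, correct in size, and class-aware", {
  co <- simulate_cohort(gusto_spec(n = 300, seed = 9))
  s1 <- subsample_cohort(co, 50, seed = 3)
  s2 <- subsample_cohort(co, 50, seed = 3)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(50L, 8L))
  expect_error(subsample_cohort(co, 301, seed = 1), "between 2 and n")

  # m = n returns the same multiset of rows
  full <- subsample_cohort(co, 300, seed = 2)
  expect_identical(sort(full$ids), sort(co$ids))

  # a cohort with one event: any usable draw has both classes, or redraws
  # were logged along the way
  rare <- cohort(c(1, rep(0, 29)), cbind(x = rnorm(30)))
  s <- subsample_cohort(rare, 5, seed = 8)
  expect_true(length(unique(s$outcome)) == 2L)
  expect_gte(attr(s, "redraws"), 0L)

  # conditioning on an exact event count
  s35 <- subsample_cohort(simulate_cohort(gusto_spec(n = 2000, seed = 1)),
                          500, seed = 5, exact_events = 35)
  expect_identical(n_events(s35), 35L)
})
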