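test_that("risk prediction matches the closed-form logistic expression", {
  co <- toy_cohort(30, seed = 5)
  null_m <- risk_model(0, c(x1 = 0, x2 = 0))
  expect_equal(predict_risks(null_m, co), rep(0.5, 30))

  prev_m <- risk_model(qlogis(0.07), c(x1 = 0, x2 = 0))
  expect_equal(predict_risks(prev_m, co), rep(0.07, 30))

  hand <- risk_model(-2, c(x = 1))
  one <- cohort(0, cbind(x = 2))
  expect_equal(predict_risks(hand, one), 0.5)

  bad <- risk_model(0, c(zz = 1))
  expect_error(predict_risks(bad, co), "zz")
})

test_that("a zero-only penalty grid reduces the lasso to the ML fit", {
  co <- toy_cohort(400, seed = 11)
  m0 <- develop_model(co, lasso_procedure(lambda = 0), seed = 1)
  ref <- glm(co$outcome ~ co$predictors, family = binomial())
  expect_equal(unname(coef(m0)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("development is deterministic given the seed and re-tunes from scratch", {
  co <- simulate_cohort(gusto_spec(n = 600, seed = 8))
  m1 <- develop_model(co, lasso_procedure(), seed = 42)
  m2 <- develop_model(co, lasso_procedure(), seed = 42)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$tuning_record$lambda, m2$tuning_record$lambda)
  m3 <- develop_model(co, lasso_procedure(), seed = 43)
  # a different fold assignment may (and here does) pick another penalty
  expect_false(identical(m3$tuning_record$lambda, m1$tuning_record$lambda))
})

test_that("the L1 norm of fitted coefficients is non-increasing in a fixed penalty", {
  co <- simulate_cohort(gusto_spec(n = 800, seed = 14))
  grid <- c(0.001, 0.005, 0.02, 0.05, 0.1)
  l1 <- vapply(grid, function(lam) {
    m <- develop_model(co, lasso_procedure(lambda = lam), seed = 1)
    sum(abs(m$coefficients))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-10))
})

test_that("a strong penalty shrinks a pure-noise predictor to zero", {
  dropped <- 0L
  for (s in 1:10) {
    spec <- synthetic_spec(
      2000, -1, c(x1 = 0.8, x2 = 0.5, noise = 0),
      list(x1 = list(kind = "normal", mean = 0, sd = 1, standardize = TRUE),
           x2 = list(kind = "bernoulli", p = 0.4),
           noise = list(kind = "normal", mean = 0, sd = 1, standardize = TRUE)),
      seed = s)
    m <- develop_model(simulate_cohort(spec),
                       lasso_procedure(lambda = 0.05), seed = s)
    if (m$coefficients[["noise"]] == 0) dropped <- dropped + 1L
    expect_gt(m$coefficients[["x1"]], 0)
  }
  expect_gte(dropped, 8L)
})

test_that("the tuned lasso recovers the generating coefficients at large n", {
  co <- simulate_cohort(gusto_spec(n = 50000, seed = 21))
  m <- develop_model(co, lasso_procedure(), seed = 3)
  truth <- attr(co, "truth")$coefficients
  # standard errors from the unpenalised fit as the sampling-noise scale
  ref <- glm(co$outcome ~ co$predictors, family = binomial())
  se <- sqrt(diag(vcov(ref)))[-1]
  expect_true(all(abs(m$coefficients - truth) < 3 * se + 0.02))
})

test_that("separated data raises a flagged fit error", {
  sep <- cohort(c(0, 0, 0, 1, 1, 1),
                cbind(x = c(-3, -2, -1, 1, 2, 3)))
  expect_error(develop_model(sep, mle_procedure(), seed = 1),
               class = "predstab_fit_error")
})

test_that("single-class cohorts are rejected for development", {
  co <- cohort(rep(0, 20), cbind(x = rnorm(20)))
  expect_error(develop_model(co, mle_procedure()), "single outcome class")
})

test_that("fitted models survive a JSON round trip", {
  co <- toy_cohort(300, seed = 2)
  m <- develop_model(co, lasso_procedure(), seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(predict_risks(back, co), predict_risks(m, co))
})
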