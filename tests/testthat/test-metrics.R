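test_that("c-statistic matches its defining all-pairs count", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.3, 10), c(1, rep(0, 9))), 0.5)
  r5 <- c(0.8, 0.4, 0.6, 0.2, 0.5)
  y5 <- c(1, 0, 1, 0, 0)
  expect_identical(c_statistic(r5, y5), oracle_cstat(r5, y5))
  expect_error(c_statistic(runif(5), rep(1, 5)), "both outcome classes")
})

test_that("c-statistic is rank-invariant and complement-symmetric", {
  for (s in 1:20) {
    n <- 10 + s
    risks <- with_seed_env(s, round(runif(n), 2))  # rounded to force ties
    y <- with_seed_env(s + 500, rbinom(n, 1, 0.4))
    if (length(unique(y)) < 2) next
    cs <- c_statistic(risks, y)
    expect_identical(cs, oracle_cstat(risks, y))
    expect_equal(c_statistic(plogis(5 * qlogis(pmin(pmax(risks, 0.01), 0.99))), y),
                 c_statistic(pmin(pmax(risks, 0.01), 0.99), y))
    expect_equal(cs + c_statistic(1 - risks, y), 1)
  }
})

test_that("Nagelkerke R2 matches direct log-likelihood arithmetic", {
  co <- cohort(c(1, 0, 1, 0, 0, 1),
               cbind(x = c(2, -1, 1, 0, -2, 3)))
  m <- risk_model(-0.3, c(x = 0.9))
  p <- plogis(-0.3 + 0.9 * co$predictors[, "x"])
  l1 <- sum(dbinom(co$outcome, 1, p, log = TRUE))
  l0 <- sum(dbinom(co$outcome, 1, mean(co$outcome), log = TRUE))
  n <- 6
  expected <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  expect_equal(nagelkerke_r2(m, co), expected)

  # intercept-only model explains nothing
  m0 <- risk_model(qlogis(mean(co$outcome)), c(x = 0))
  expect_equal(nagelkerke_r2(m0, co), 0)

  # near-perfect predictions approach 1
  mstar <- risk_model(-0.3 * 50, c(x = 0.9 * 50))
  co_sep <- cohort(as.numeric(p > 0.5), co$predictors)
  expect_gt(nagelkerke_r2(mstar, co_sep), 0.95)
})

test_that("net benefit follows its defining arithmetic", {
  expect_equal(net_benefit(c(0.8, 0.6, 0.4, 0.2), c(1, 1, 0, 0), 0.5), 0.5)
  # nobody classified positive
  expect_equal(net_benefit(rep(0.01, 8), rbinom(8, 1, 0.5), 0.5), 0)
  # everyone positive: prevalence - (1 - prevalence) t/(1-t)
  y <- c(1, 1, 0, 0, 0)
  expect_equal(net_benefit(rep(0.9, 5), y, 0.2),
               0.4 - 0.6 * 0.2 / 0.8)
  # ties at the threshold classify positive
  expect_equal(net_benefit(c(0.1, 0.09), c(1, 0), 0.1), 0.5)
  expect_error(net_benefit(runif(4), c(1, 0, 1, 0), 1.2), "threshold")
})

test_that("calibration curves track direction of miscalibration", {
  with_seed_env(99, {
    p <- plogis(rnorm(20000, -1.5, 1))
    y <- rbinom(20000, 1, p)
  })
  cc <- calibration_curve(p, y)
  expect_true(all(diff(cc$grid) > 0))
  expect_true(all(cc$smoothed_observed >= 0 & cc$smoothed_observed <= 1))
  expect_lt(max(abs(cc$smoothed_observed - cc$grid)), 0.05)

  # risks shifted up by 0.1: observed risk falls below the diagonal
  shifted <- pmin(p + 0.1, 0.999)
  cs <- calibration_curve(shifted, y)
  bulk <- cs$grid > quantile(shifted, 0.1) & cs$grid < quantile(shifted, 0.9)
  expect_true(all(cs$smoothed_observed[bulk] < cs$grid[bulk]))

  # evaluation clips to the support range
  expect_true(is.na(eval_curve(cc, cc$support_range[2] + 0.05)))
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibration_curve(runif(10), rbinom(10, 1, 0.5)),
               "at least 50")
  expect_error(calibration_curve(rep(0.3, 100), rbinom(100, 1, 0.3)),
               "degenerate")
  expect_error(calibration_curve(runif(100, 0.1, 0.9), rep(0, 100)),
               "constant")
})

test_that("events per parameter reports the ratio and its rounding", {
  full <- events_per_parameter(2851, 8)
  expect_equal(unclass(full), 356.375, ignore_attr = TRUE)
  expect_identical(attr(full, "rounded"), 356L)
  small <- events_per_parameter(35, 8)
  expect_equal(unclass(small), 4.375, ignore_attr = TRUE)
  expect_identical(attr(small, "rounded"), 4L)
  expect_equal(unclass(events_per_parameter(0, 8)), 0, ignore_attr = TRUE)
  expect_error(events_per_parameter(10, 0), "at least 1")
})
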