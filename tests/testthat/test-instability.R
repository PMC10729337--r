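test_that("the bootstrap multiverse is reproducible bitwise", {
  co <- toy_cohort(150, seed = 6)
  b1 <- suppressWarnings(run_bootstrap(co, mle_procedure(), B = 8, seed = 17))
  b2 <- suppressWarnings(run_bootstrap(co, mle_procedure(), B = 8, seed = 17))
  expect_identical(b1$multiverse, b2$multiverse)
  expect_identical(b1$original, b2$original)
  expect_identical(dim(b1$multiverse), c(150L, 8L))
  b3 <- suppressWarnings(run_bootstrap(co, mle_procedure(), B = 8, seed = 18))
  expect_false(identical(b3$multiverse, b1$multiverse))
})

test_that("a full instability report is reproducible bitwise", {
  co <- toy_cohort(120, seed = 3)
  r1 <- suppressWarnings(instability(co, mle_procedure(), B = 10, seed = 5,
                                     thresholds = c(0.2, 0.4)))
  r2 <- suppressWarnings(instability(co, mle_procedure(), B = 10, seed = 5,
                                     thresholds = c(0.2, 0.4)))
  expect_identical(r1$mape, r2$mape)
  expect_identical(r1$intervals, r2$intervals)
  expect_identical(r1$cii, r2$cii)
  expect_identical(r1$discrimination, r2$discrimination)
  expect_identical(r1$utility, r2$utility)
})

test_that("a data-ignoring procedure collapses the multiverse onto the original", {
  co <- toy_cohort(100, seed = 9)
  fixed <- risk_model(-0.5, c(x1 = 0.7, x2 = 0.3))
  bp <- suppressWarnings(run_bootstrap(co, constant_procedure(fixed),
                                       B = 6, seed = 1))
  expect_true(all(bp$multiverse == bp$original))
  expect_equal(as.numeric(mape_per_individual(bp)), rep(0, 100))
  ints <- prediction_intervals(bp)
  expect_equal(unname(ints[, "lower"]), unname(bp$original))
  expect_equal(unname(ints[, "upper"]), unname(bp$original))
  expect_equal(classification_instability_index(bp, 0.3), rep(0, 100))
  d <- discrimination_instability(bp, co)
  expect_equal(unname(diff(d$percentiles)), 0)
  u <- clinical_utility_instability(bp, co, c(0.1, 0.3))
  expect_true(all(apply(u$net_benefits, 2, function(x) diff(range(x))) == 0))
  cal <- calibration_instability(bp, co)
  expect_equal(max(cal$spread$width), 0)
})

test_that("MAPE, CII and intervals agree with hand-worked examples", {
  p <- 0.2
  M <- matrix(c(0.1, 0.3, 0.2), nrow = 1)
  bp <- make_preds(p, M)
  expect_equal(as.numeric(mape_per_individual(bp)), 0.2 / 3)

  bp2 <- make_preds(0.12, matrix(c(0.05, 0.15, 0.09, 0.11), nrow = 1))
  expect_equal(classification_instability_index(bp2, 0.1), 0.5)

  row <- seq(0.01, 0.99, length.out = 100)
  bp3 <- make_preds(0.5, matrix(with_seed_env(4, sample(row)), nrow = 1))
  ints <- prediction_intervals(bp3, level = 0.95)
  expect_identical(unname(ints[1, "lower"]),
                   oracle_quantile(row, (1 - 0.95) / 2))
  expect_identical(unname(ints[1, "upper"]),
                   oracle_quantile(row, 1 - (1 - 0.95) / 2))
  expect_true(ints[1, "lower"] >= min(row) && ints[1, "upper"] <= max(row))
  expect_error(prediction_intervals(bp3, level = 1.5), "level")
})

test_that("MAPE variance attribute matches the sample variance of absolute errors", {
  M <- matrix(runif(40), nrow = 4)
  p <- runif(4)
  bp <- make_preds(p, M)
  v <- attr(mape_per_individual(bp), "abs_error_variance")
  expect_equal(v, apply(abs(M - p), 1, var))
})

test_that("CII is invariant to permuting bootstrap columns", {
  with_seed_env(12, {
    M <- matrix(runif(60), nrow = 10)
    p <- runif(10)
  })
  bp <- make_preds(p, M)
  perm <- make_preds(p, M[, c(4, 2, 6, 1, 5, 3)])
  expect_identical(classification_instability_index(bp, 0.3),
                   classification_instability_index(perm, 0.3))
})

test_that("c-statistic instability is rank-invariant across columns", {
  co <- toy_cohort(80, seed = 2)
  base <- plogis(qlogis(runif(80, 0.05, 0.95)))
  M <- cbind(base, plogis(2 * qlogis(base)), plogis(0.5 * qlogis(base) + 1))
  bp <- make_preds(base, M)
  d <- discrimination_instability(bp, co)
  expect_equal(unname(d$c_statistics), rep(unname(d$c_statistics[1]), 3))
})

test_that("degenerate resamples are redrawn and logged, with a hard cap", {
  # tiny cohort with a single event: many resamples miss it
  rare <- cohort(c(1, rep(0, 24)), cbind(x = with_seed_env(1, rnorm(25))))
  lin <- development_procedure(function(cohort, seed) {
    # deliberately trivial fit so only the resample's class mix matters
    risk_model(qlogis(max(mean(cohort$outcome), 0.01)), c(x = 0))
  }, "trivial")
  bp <- suppressWarnings(run_bootstrap(rare, lin, B = 10, seed = 3))
  expect_identical(ncol(bp$multiverse), 10L)
  expect_gte(bp$provenance$redraws, 1L)
  expect_length(bp$provenance$failures, bp$provenance$redraws)

  # succeeds for the original fit, then fails every bootstrap refit
  calls <- new.env()
  calls$k <- 0L
  always_fails <- development_procedure(function(cohort, seed) {
    calls$k <- calls$k + 1L
    if (calls$k > 1L) stop("no fit today")
    risk_model(-1, c(x1 = 0.5, x2 = 0.2))
  }, "broken")
  co <- toy_cohort(50, seed = 5)
  expect_error(
    suppressWarnings(run_bootstrap(co, always_fails, B = 2, seed = 1,
                                   max_redraws = 5)),
    "redraw cap")
})

test_that("subgroup MAPE reduces to the global summary and respects symmetry", {
  co <- toy_cohort(90, seed = 13)
  bp <- suppressWarnings(run_bootstrap(co, mle_procedure(), B = 15, seed = 2))
  one <- subgroup_mape(bp, rep("all", 90))
  mape <- mape_per_individual(bp)
  expect_equal(one$mean_mape, mean(mape))
  expect_equal(one$max_mape, max(mape))

  # identical groups by construction: duplicate every individual
  dup <- make_preds(rep(bp$original, 2),
                    rbind(bp$multiverse, bp$multiverse))
  sg <- subgroup_mape(dup, rep(c("a", "b"), each = 90))
  expect_equal(sg$mean_mape[1], sg$mean_mape[2])
  expect_equal(sg$max_mape[1], sg$max_mape[2])
  expect_error(subgroup_mape(bp, rep("x", 10)), "every individual")
  expect_error(subgroup_mape(bp, c(NA, rep("x", 89))), "missing")
})

test_that("a rare-pattern subgroup shows larger instability", {
  with_seed_env(7, {
    n <- 600
    rare <- rep(c(0, 1), c(570, 30))
    x <- rnorm(n) + 3 * rare
    co <- cohort(rbinom(n, 1, plogis(-2 + x)), cbind(x = x))
  })
  bp <- suppressWarnings(run_bootstrap(co, mle_procedure(), B = 30, seed = 3))
  sg <- subgroup_mape(bp, ifelse(rare == 1, "rare", "common"))
  expect_gt(sg$mean_mape[sg$group == "rare"],
            sg$mean_mape[sg$group == "common"])
})

test_that("learning curves fall with sample size and handle edge cases", {
  co <- simulate_cohort(gusto_spec(n = 2000, seed = 11))
  lc <- suppressWarnings(
    learning_curve(co, mle_procedure(), sizes = c(150, 1500), B = 40,
                   seed = 5))
  expect_identical(lc$size, c(150L, 1500L))
  expect_lt(lc$mean_mape[2], lc$mean_mape[1])

  empty <- learning_curve(co, mle_procedure(), sizes = integer(0))
  expect_identical(nrow(empty), 0L)

  # a size equal to n reproduces a direct engine run on the same seed path
  seeds <- predstab:::derive_seeds(9, 2)
  lcn <- suppressWarnings(
    learning_curve(co, mle_procedure(), sizes = 2000, B = 5, seed = 9))
  direct <- suppressWarnings(
    run_bootstrap(co, mle_procedure(), B = 5, seed = seeds[2]))
  expect_identical(lcn$mean_mape, mean(mape_per_individual(direct)))
  expect_error(learning_curve(co, mle_procedure(), sizes = 4000), "exceed")
})

test_that("calibration instability contrasts large and small cohorts", {
  big <- simulate_cohort(gusto_spec(n = 4000, seed = 21))
  small <- subsample_cohort(big, 300, seed = 4)
  bp_big <- suppressWarnings(run_bootstrap(big, mle_procedure(), B = 25, seed = 6))
  bp_small <- suppressWarnings(run_bootstrap(small, mle_procedure(), B = 25, seed = 6))
  cal_big <- calibration_instability(bp_big, big, max_curves = 25)
  cal_small <- calibration_instability(bp_small, small, max_curves = 25)
  expect_true(all(cal_big$spread$width >= 0))
  expect_gt(mean(cal_small$spread$width), mean(cal_big$spread$width))
  # net-benefit spread widens too
  nb_big <- clinical_utility_instability(bp_big, big, 0.1)
  nb_small <- clinical_utility_instability(bp_small, small, 0.1)
  expect_gt(diff(range(nb_small$net_benefits)),
            diff(range(nb_big$net_benefits)))
})
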