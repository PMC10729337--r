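# The bootstrap instability engine: replay the model development process
# across B bootstrap resamples, collect each individual's multiverse of
# predicted risks, and summarise its spread.

#' Replay model development across bootstrap resamples
#'
#' The core resampling loop. Develops the model once on the original
#' cohort, then draws `B` bootstrap samples (with replacement, size n),
#' re-runs the full development procedure — including tuning — in each,
#' and applies every bootstrap model back to the *original* cohort. The
#' resulting n x B matrix is the sampled multiverse of predictions.
#'
#' Degenerate resamples (a single outcome class, or a development fit that
#' fails) are redrawn with a fresh derived seed; redraws are logged in the
#' provenance and capped.
#'
#' @param cohort a [cohort()] with both outcome classes.
#' @param procedure a [development_procedure()]; default the packaged
#'   cross-validated lasso.
#' @param B number of bootstrap models. At least 200 is recommended for
#'   stable instability summaries; a warning is issued below that.
#' @param seed master seed; the whole object is reproducible bitwise from
#'   `(cohort, procedure, B, seed)`.
#' @param max_redraws total redraw budget across the run.
#' @return An object of class `"bootstrap_predictions"`: list with
#'   `original` (length-n vector of original-model predictions),
#'   `multiverse` (n x B matrix, column b from the model developed on
#'   bootstrap sample b), `B`, `model` (the original [risk_model()]) and
#'   `provenance` (seeds, procedure name, redraw log).
#' @examples
#' co <- simulate_cohort(gusto_spec(n = 400, seed = 5))
#' bp <- run_bootstrap(co, mle_procedure(), B = 20, seed = 9)
#' bp
#' @export
run_bootstrap <- function(cohort, procedure = lasso_procedure(), B = 200L,
                          seed = 1L, max_redraws = 50L) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(procedure, "development_procedure"))
  assert_two_classes(cohort)
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be at least 1", call. = FALSE)
  if (B < 200L) {
    warning(sprintf(
      "B = %d is below the recommended minimum of 200 bootstrap models", B),
      call. = FALSE)
  }
  n <- length(cohort$outcome)
  # seed layout: [1] original fit; [2..B+1] per-column fits;
  # [B+2..2B+1] per-column resample draws; remainder redraw reserve
  seeds <- derive_seeds(seed, 2L * B + 1L + 2L * max_redraws)
  fit_seeds <- seeds[2L:(B + 1L)]
  draw_seeds <- seeds[(B + 2L):(2L * B + 1L)]
  reserve <- seeds[(2L * B + 2L):length(seeds)]
  model <- develop_model(cohort, procedure, seed = seeds[1L])
  original <- predict_risks(model, cohort)
  multiverse <- matrix(NA_real_, n, B)
  redraws <- 0L
  failures <- character(0)
  for (b in seq_len(B)) {
    dseed <- draw_seeds[b]
    fseed <- fit_seeds[b]
    repeat {
      idx <- with_seed(dseed, sample.int(n, n, replace = TRUE))
      boot <- cohort_rows(cohort, idx)
      fit <- if (length(unique(boot$outcome)) < 2L) {
        simpleError("bootstrap sample contains a single outcome class")
      } else {
        tryCatch(develop_model(boot, procedure, seed = fseed),
                 predstab_fit_error = function(e) e,
                 error = function(e) e)
      }
      if (!inherits(fit, "error")) break
      redraws <- redraws + 1L
      failures <- c(failures,
                    sprintf("column %d: %s", b, conditionMessage(fit)))
      if (redraws > max_redraws) {
        stop(sprintf(paste0(
          "bootstrap redraw cap (%d) exceeded; the cohort is too small or ",
          "degenerate for a stable instability assessment — consider more data"),
          max_redraws), call. = FALSE)
      }
      dseed <- reserve[2L * redraws - 1L]
      fseed <- reserve[2L * redraws]
    }
    multiverse[, b] <- predict_risks(fit, cohort)
  }
  structure(
    list(original = original, multiverse = multiverse, B = B, model = model,
         provenance = list(seed = as.integer(seed),
                           procedure = procedure$name,
                           n = n, redraws = redraws, failures = failures)),
    class = "bootstrap_predictions")
}

#' @export
print.bootstrap_predictions <- function(x, ...) {
  cat(sprintf(
    "Bootstrap multiverse: n = %d individuals x B = %d models (%s procedure)\n",
    length(x$original), x$B, x$provenance$procedure))
  cat(sprintf("Redraws of degenerate resamples: %d\n", x$provenance$redraws))
  invisible(x)
}

assert_preds <- function(preds) {
  stopifnot(inherits(preds, "bootstrap_predictions"))
  invisible(preds)
}

#' Per-individual mean absolute prediction error (MAPE)
#'
#' `MAPE_i = (1/B) sum_b |p_bi - p_i|`: the mean absolute difference
#' between an individual's B bootstrap-model predictions and their
#' original-model prediction. The per-individual variance of the absolute
#' errors is attached as attribute `"abs_error_variance"`.
#'
#' @param preds a [run_bootstrap()] result.
#' @return Numeric vector of length n, non-negative.
#' @export
mape_per_individual <- function(preds) {
  assert_preds(preds)
  abs_err <- abs(preds$multiverse - preds$original)
  mape <- rowSums(abs_err) / preds$B
  v <- if (preds$B >= 2L) {
    rowSums((abs_err - mape)^2) / (preds$B - 1L)
  } else rep(NA_real_, length(mape))
  attr(mape, "abs_error_variance") <- v
  mape
}

#' Per-individual prediction-instability intervals
#'
#' Empirical percentiles of each individual's B bootstrap predictions,
#' e.g. the 2.5th and 97.5th for a 95% interval. Percentiles use the
#' standard linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param preds a [run_bootstrap()] result with `B >= 2`.
#' @param level interval coverage in (0, 1), default 0.95.
#' @return n x 2 matrix with columns `lower`, `upper`.
#' @export
prediction_intervals <- function(preds, level = 0.95) {
  assert_preds(preds)
  check_scalar_prob(level, "level")
  if (preds$B < 2L) stop("intervals require B >= 2", call. = FALSE)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- t(apply(preds$multiverse, 1L, stats::quantile, probs = probs,
                 type = 7, names = FALSE))
  dimnames(out) <- list(NULL, c("lower", "upper"))
  attr(out, "level") <- level
  out
}

#' Per-individual classification instability index (CII)
#'
#' The proportion of bootstrap models whose prediction for an individual
#' falls on the opposite side of the decision threshold from the original
#' model's prediction — an estimate of the probability that the original
#' classification would differ in another model from the multiverse.
#' A risk at or above the threshold classifies positive.
#'
#' @param preds a [run_bootstrap()] result.
#' @param threshold decision threshold in (0, 1).
#' @return Numeric vector in \[0, 1\], length n.
#' @export
classification_instability_index <- function(preds, threshold) {
  assert_preds(preds)
  check_scalar_prob(threshold, "threshold")
  orig_pos <- preds$original >= threshold
  rowMeans((preds$multiverse >= threshold) != orig_pos)
}

#' Instability of the c-statistic across the multiverse
#'
#' Applies each bootstrap model to the original cohort and computes its
#' c-statistic against the observed outcomes.
#'
#' @param preds a [run_bootstrap()] result.
#' @param cohort the original [cohort()] the multiverse was computed on.
#' @return List with `c_statistics` (length B), `original` (the original
#'   model's c-statistic) and `percentiles` (2.5th/97.5th).
#' @export
discrimination_instability <- function(preds, cohort) {
  assert_preds(preds)
  assert_two_classes(cohort, "the c-statistic")
  cs <- apply(preds$multiverse, 2L, c_statistic, outcomes = cohort$outcome)
  list(c_statistics = cs,
       original = c_statistic(preds$original, cohort$outcome),
       percentiles = stats::quantile(cs, c(0.025, 0.975), type = 7))
}

#' Instability of net benefit across the multiverse
#'
#' Net benefit of each bootstrap model on the original cohort, per
#' decision threshold, with the original model's value and the empirical
#' 2.5th/97.5th percentile spread.
#'
#' @param preds a [run_bootstrap()] result.
#' @param cohort the original [cohort()].
#' @param thresholds numeric vector of decision thresholds in (0, 1).
#' @return List with `net_benefits` (B x length(thresholds) matrix),
#'   `original` and `percentiles` (2 x length(thresholds)).
#' @export
clinical_utility_instability <- function(preds, cohort, thresholds = 0.1) {
  assert_preds(preds)
  for (t in thresholds) check_scalar_prob(t, "thresholds")
  nb <- sapply(thresholds, function(t) {
    apply(preds$multiverse, 2L, net_benefit, outcomes = cohort$outcome,
          threshold = t)
  })
  nb <- matrix(nb, nrow = preds$B,
               dimnames = list(NULL, sprintf("t=%g", thresholds)))
  orig <- vapply(thresholds, function(t) {
    net_benefit(preds$original, cohort$outcome, t)
  }, numeric(1))
  names(orig) <- colnames(nb)
  list(net_benefits = nb, original = orig,
       percentiles = apply(nb, 2L, stats::quantile, c(0.025, 0.975),
                           type = 7))
}

#' Instability of the calibration curve across the multiverse
#'
#' Fits a smoothed calibration curve for each bootstrap model applied to
#' the original cohort (by default the first `max_curves = 200` models,
#' enough for a dense overlay), plus the original model's curve, and
#' summarises the spread of the curves on the original curve's grid.
#'
#' @param preds a [run_bootstrap()] result.
#' @param cohort the original [cohort()].
#' @param smoother a [cal_smoother()].
#' @param max_curves maximum number of bootstrap curves fitted.
#' @return List of class `"calibration_bundle"`: `original` (the original
#'   model's [calibration_curve()]), `curves` (list of bootstrap curves),
#'   `spread` (data frame: grid point, sd, width of the curve band there),
#'   `skipped` (count of degenerate curves skipped).
#' @export
calibration_instability <- function(preds, cohort, smoother = cal_smoother(),
                                    max_curves = 200L) {
  assert_preds(preds)
  orig_curve <- calibration_curve(preds$original, cohort$outcome, smoother)
  ks <- seq_len(min(preds$B, max_curves))
  skipped <- 0L
  curves <- list()
  for (b in ks) {
    cv <- tryCatch(
      calibration_curve(preds$multiverse[, b], cohort$outcome, smoother),
      error = function(e) NULL)
    if (is.null(cv)) skipped <- skipped + 1L else curves[[length(curves) + 1L]] <- cv
  }
  if (!length(curves)) {
    stop("all bootstrap calibration curves were degenerate", call. = FALSE)
  }
  onto <- orig_curve$grid
  vals <- vapply(curves, eval_curve, numeric(length(onto)), at = onto)
  spread <- data.frame(
    grid = onto,
    sd = apply(vals, 1L, stats::sd, na.rm = TRUE),
    width = apply(vals, 1L, function(v) diff(range(v, na.rm = TRUE))))
  structure(list(original = orig_curve, curves = curves, spread = spread,
                 skipped = skipped),
            class = "calibration_bundle")
}

#' @export
print.calibration_bundle <- function(x, ...) {
  cat(sprintf(
    "Calibration instability: %d bootstrap curves (%d degenerate skipped)\n",
    length(x$curves), x$skipped))
  cat(sprintf("Mean curve-band width across grid: %.4f (max %.4f)\n",
              mean(x$spread$width), max(x$spread$width)))
  invisible(x)
}

#' MAPE summarised within subgroups
#'
#' Instability is often unevenly distributed: small or atypical subgroups
#' (e.g. defined by ethnicity) can carry much larger prediction
#' instability than the cohort average, which matters for model fairness.
#'
#' @param preds a [run_bootstrap()] result.
#' @param groups vector of per-individual subgroup labels, length n, no
#'   missing values.
#' @return Data frame, one row per subgroup (in label sort order): `group`,
#'   `n`, `mean_mape`, `median_mape`, `p2.5`, `p97.5`, `max_mape`.
#' @export
subgroup_mape <- function(preds, groups) {
  assert_preds(preds)
  if (length(groups) != length(preds$original)) {
    stop("`groups` must label every individual", call. = FALSE)
  }
  if (anyNA(groups)) stop("`groups` contains missing labels", call. = FALSE)
  mape <- as.numeric(mape_per_individual(preds))
  gs <- sort(unique(as.character(groups)))
  rows <- lapply(gs, function(g) {
    m <- mape[as.character(groups) == g]
    q <- stats::quantile(m, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
    data.frame(group = g, n = length(m), mean_mape = mean(m),
               median_mape = q[2], p2.5 = q[1], p97.5 = q[3],
               max_mape = max(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MAPE summary across individuals
#' @noRd
summarise_mape <- function(mape) {
  q <- stats::quantile(mape, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  c(mean = mean(mape), median = q[2], p2.5 = q[1], p97.5 = q[3],
    max = max(mape))
}

#' Learning curve of prediction instability against sample size
#'
#' For each requested development sample size, draws a random sub-sample
#' of the cohort and runs the full bootstrap instability engine on it.
#' Falling MAPE with growing n indicates how much additional data would
#' stabilise the model; a flat, low curve indicates the data already
#' suffice.
#'
#' @param cohort a [cohort()].
#' @param procedure a [development_procedure()].
#' @param sizes vector of development sample sizes (each <= n). A size
#'   equal to n uses the cohort as-is.
#' @param B bootstrap models per size.
#' @param seed master seed; per-size sub-sample and engine seeds are
#'   derived from it.
#' @return Data frame: `size`, `n_events`, `mean_mape`, `max_mape`,
#'   `subsample_seed`, `engine_seed`.
#' @export
learning_curve <- function(cohort, procedure = lasso_procedure(),
                           sizes, B = 100L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  sizes <- as.integer(sizes)
  if (!length(sizes)) {
    return(data.frame(size = integer(), n_events = integer(),
                      mean_mape = numeric(), max_mape = numeric(),
                      subsample_seed = integer(), engine_seed = integer()))
  }
  n <- length(cohort$outcome)
  if (any(sizes > n)) stop("`sizes` cannot exceed the cohort size", call. = FALSE)
  seeds <- matrix(derive_seeds(seed, 2L * length(sizes)), ncol = 2L)
  rows <- lapply(seq_along(sizes), function(k) {
    m <- sizes[k]
    sub <- if (m == n) cohort else subsample_cohort(cohort, m, seeds[k, 1L])
    bp <- run_bootstrap(sub, procedure, B = B, seed = seeds[k, 2L])
    mape <- mape_per_individual(bp)
    data.frame(size = m, n_events = as.integer(sum(sub$outcome)),
               mean_mape = mean(mape), max_mape = max(mape),
               subsample_seed = if (m == n) NA_integer_ else seeds[k, 1L],
               engine_seed = seeds[k, 2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
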