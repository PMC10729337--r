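# The main user-facing entry point: run the whole instability assessment
# and return one classed object with print/summary/plot methods.

#' Assess the instability of a clinical prediction model's predictions
#'
#' The one-stop analysis: develops the model on the cohort, replays the
#' development process across `B` bootstrap resamples
#' ([run_bootstrap()]), and summarises the resulting multiverse of
#' predictions — per-individual MAPE and instability intervals, the
#' classification instability index at each decision threshold, and the
#' per-bootstrap-model c-statistic, net benefit and calibration curves.
#'
#' @param cohort a [cohort()] with both outcome classes.
#' @param procedure a [development_procedure()]; default the packaged
#'   cross-validated lasso.
#' @param B number of bootstrap models (>= 200 recommended).
#' @param seed master seed; the full report is reproducible bitwise from
#'   its arguments.
#' @param thresholds decision threshold(s) in (0, 1) for the
#'   classification instability index and net benefit.
#' @param level coverage of the per-individual instability intervals.
#' @param smoother a [cal_smoother()] for calibration curves.
#' @param subgroups optional per-individual subgroup labels for fairness
#'   checks.
#' @param calibration fit calibration instability curves? Requires
#'   `length(cohort) >= smoother$min_n`.
#' @param max_curves maximum number of bootstrap calibration curves.
#' @param max_redraws redraw budget for degenerate bootstrap resamples.
#' @return An object of class `"instability_report"`; see
#'   [summary.instability_report()], [plot.instability_report()] and
#'   [write_report()].
#' @examples
#' co <- simulate_cohort(gusto_spec(n = 500, seed = 2))
#' rep <- instability(co, mle_procedure(), B = 30, seed = 4)
#' summary(rep)
#' @export
instability <- function(cohort, procedure = lasso_procedure(), B = 200L,
                        seed = 1L, thresholds = 0.1, level = 0.95,
                        smoother = cal_smoother(), subgroups = NULL,
                        calibration = TRUE, max_curves = 200L,
                        max_redraws = 50L) {
  preds <- run_bootstrap(cohort, procedure, B = B, seed = seed,
                         max_redraws = max_redraws)
  mape <- mape_per_individual(preds)
  intervals <- prediction_intervals(preds, level = level)
  cii <- vapply(thresholds, function(t) {
    classification_instability_index(preds, t)
  }, numeric(length(preds$original)))
  cii <- matrix(cii, ncol = length(thresholds),
                dimnames = list(NULL, sprintf("t=%g", thresholds)))
  disc <- discrimination_instability(preds, cohort)
  util <- clinical_utility_instability(preds, cohort, thresholds)
  calib <- if (isTRUE(calibration) &&
               length(cohort$outcome) >= smoother$min_n) {
    calibration_instability(preds, cohort, smoother, max_curves)
  } else NULL
  sg <- if (!is.null(subgroups)) subgroup_mape(preds, subgroups) else NULL
  structure(
    list(preds = preds, cohort = cohort,
         mape = mape, mape_summary = summarise_mape(mape),
         intervals = intervals, cii = cii,
         discrimination = disc, utility = util, calibration = calib,
         subgroups = sg,
         config = list(B = as.integer(B), seed = as.integer(seed),
                       thresholds = thresholds, level = level,
                       procedure = procedure$name,
                       n = length(cohort$outcome),
                       n_events = as.integer(sum(cohort$outcome)))),
    class = "instability_report")
}

#' @export
print.instability_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Prediction instability report: n = %d (%d events), B = %d (%s), seed %d\n",
    cfg$n, cfg$n_events, cfg$B, cfg$procedure, cfg$seed))
  cat(sprintf("Mean MAPE %.4g, max MAPE %.4g\n",
              x$mape_summary[["mean"]], x$mape_summary[["max"]]))
  invisible(x)
}

#' Summarise an instability report
#'
#' @param object an [instability()] report.
#' @param ... unused.
#' @return `object`, invisibly; prints MAPE, c-statistic, net-benefit and
#'   calibration instability summaries.
#' @export
summary.instability_report <- function(object, ...) {
  x <- object
  cfg <- x$config
  print(x)
  ms <- x$mape_summary
  cat(sprintf("MAPE across individuals: mean %.4g | 2.5%% %.4g | median %.4g | 97.5%% %.4g | max %.4g\n",
              ms[["mean"]], ms[["p2.5"]], ms[["median"]], ms[["p97.5"]],
              ms[["max"]]))
  d <- x$discrimination
  cat(sprintf("c-statistic: original %.3f; bootstrap 95%% range [%.3f, %.3f]\n",
              d$original, d$percentiles[[1]], d$percentiles[[2]]))
  for (j in seq_len(ncol(x$cii))) {
    cat(sprintf(
      "Classification instability (%s): mean %.4g, max %.4g; net benefit %.4g [%.4g, %.4g]\n",
      colnames(x$cii)[j], mean(x$cii[, j]), max(x$cii[, j]),
      x$utility$original[[j]], x$utility$percentiles[1, j],
      x$utility$percentiles[2, j]))
  }
  if (!is.null(x$calibration)) {
    cat(sprintf("Calibration: %d bootstrap curves, mean band width %.4f\n",
                length(x$calibration$curves), mean(x$calibration$spread$width)))
  }
  if (!is.null(x$subgroups)) {
    cat("Subgroup MAPE:\n")
    print(x$subgroups, digits = 4)
  }
  if (x$preds$provenance$redraws > 0) {
    cat(sprintf("Degenerate bootstrap resamples redrawn: %d\n",
                x$preds$provenance$redraws))
  }
  invisible(x)
}

#' Per-individual results of an instability report as a data frame
#' @param x an [instability()] report.
#' @param ... unused.
#' @return Data frame: id, original prediction, MAPE, absolute-error
#'   variance, interval bounds, and one CII column per threshold.
#' @export
as.data.frame.instability_report <- function(x, ...) {
  df <- data.frame(
    id = x$cohort$ids,
    prediction = x$preds$original,
    mape = as.numeric(x$mape),
    abs_error_variance = attr(x$mape, "abs_error_variance"),
    lower = x$intervals[, "lower"],
    upper = x$intervals[, "upper"])
  cii <- as.data.frame(x$cii)
  names(cii) <- sprintf("cii_%s", colnames(x$cii))
  cbind(df, cii)
}

#' Write an instability report to a directory
#'
#' Emits everything the plots are drawn from, so figures are derived
#' views and never the only record: `individuals.csv` (id, prediction,
#' MAPE, interval bounds, CII per threshold), `bootstrap.csv` (b,
#' c-statistic, net benefit per threshold), `curves.csv` (curve id 0 =
#' original model), `multiverse.csv` (the raw n x B prediction matrix)
#' and `summary.json` (config, seeds, redraw log, MAPE summary).
#'
#' @param report an [instability()] report.
#' @param dir output directory (created if needed).
#' @param multiverse also write the raw n x B matrix (needed to re-render
#'   the prediction instability plot later).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, multiverse = TRUE) {
  stopifnot(inherits(report, "instability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report),
                   file.path(dir, "individuals.csv"), row.names = FALSE)
  boot <- data.frame(b = seq_len(report$config$B),
                     c_statistic = report$discrimination$c_statistics)
  nb <- as.data.frame(report$utility$net_benefits)
  names(nb) <- sprintf("nb_%s", colnames(report$utility$net_benefits))
  utils::write.csv(cbind(boot, nb), file.path(dir, "bootstrap.csv"),
                   row.names = FALSE)
  if (!is.null(report$calibration)) {
    all_curves <- c(list(report$calibration$original),
                    report$calibration$curves)
    rows <- lapply(seq_along(all_curves), function(k) {
      cv <- all_curves[[k]]
      data.frame(curve = k - 1L, grid = cv$grid,
                 smoothed_observed = cv$smoothed_observed)
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "curves.csv"),
                     row.names = FALSE)
  }
  if (isTRUE(multiverse)) {
    mv <- as.data.frame(report$preds$multiverse)
    names(mv) <- sprintf("b%d", seq_len(report$config$B))
    utils::write.csv(cbind(data.frame(id = report$cohort$ids), mv),
                     file.path(dir, "multiverse.csv"), row.names = FALSE)
  }
  if (!is.null(report$subgroups)) {
    utils::write.csv(report$subgroups, file.path(dir, "subgroups.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = report$config,
         mape_summary = as.list(report$mape_summary),
         c_statistic = list(
           original = report$discrimination$original,
           p2.5 = report$discrimination$percentiles[[1]],
           p97.5 = report$discrimination$percentiles[[2]]),
         provenance = report$preds$provenance[
           c("seed", "procedure", "n", "redraws", "failures")],
         model = list(intercept = report$preds$model$intercept,
                      coefficients = as.list(report$preds$model$coefficients))),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
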