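# Scalar performance and calibration machinery, used for the original
# model and for every bootstrap model when summarising instability.

#' Concordance statistic (c-statistic / AUROC)
#'
#' The proportion of all event/non-event pairs in which the model assigns
#' the higher risk to the individual with the event; tied risks count 1/2.
#' Computed via midranks in O(n log n); equals the all-pairs count exactly.
#'
#' @param risks numeric vector of predicted risks.
#' @param outcomes binary 0/1 vector, both classes present.
#' @return Value in \[0, 1\].
#' @examples
#' c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
c_statistic <- function(risks, outcomes) {
  stopifnot(length(risks) == length(outcomes))
  if (anyNA(risks) || anyNA(outcomes)) stop("missing values", call. = FALSE)
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    stop("c-statistic requires both outcome classes", call. = FALSE)
  }
  r <- rank(risks)
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nagelkerke's R-squared
#'
#' Cox–Snell `R2 = 1 - exp((2/n) (l0 - l1))` rescaled by its attainable
#' maximum `1 - exp((2/n) l0)`, where `l0` is the intercept-only and `l1`
#' the model log-likelihood on the cohort.
#'
#' @param model a [risk_model()].
#' @param cohort a [cohort()] with both outcome classes.
#' @return Value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(model, cohort) {
  assert_two_classes(cohort, "Nagelkerke R-squared")
  nagelkerke_from_risks(predict_risks(model, cohort), cohort$outcome)
}

nagelkerke_from_risks <- function(risks, outcomes) {
  n <- length(outcomes)
  eps <- .Machine$double.eps
  p <- pmin(pmax(risks, eps), 1 - eps)
  l1 <- sum(outcomes * log(p) + (1 - outcomes) * log1p(-p))
  pbar <- mean(outcomes)
  l0 <- sum(outcomes * log(pbar) + (1 - outcomes) * log1p(-pbar))
  cox_snell <- 1 - exp((2 / n) * (l0 - l1))
  cox_snell / (1 - exp((2 / n) * l0))
}

#' Net benefit at a risk threshold
#'
#' `NB = TP/n - (FP/n) * t/(1 - t)` where an individual is classified
#' positive when their predicted risk is at or above the threshold `t`
#' (ties at the threshold classify positive). Net benefit weighs false
#' positives by the odds of the threshold, so it expresses clinical
#' utility in units of net true positives per individual.
#'
#' @param risks numeric vector of predicted risks.
#' @param outcomes binary 0/1 vector.
#' @param threshold decision threshold in (0, 1).
#' @return Net benefit (can be negative).
#' @examples
#' net_benefit(c(0.8, 0.6, 0.4, 0.2), c(1, 1, 0, 0), 0.5)  # 0.5
#' @export
net_benefit <- function(risks, outcomes, threshold) {
  check_scalar_prob(threshold, "threshold")
  stopifnot(length(risks) == length(outcomes))
  n <- length(risks)
  pos <- risks >= threshold
  tp <- sum(pos & outcomes == 1)
  fp <- sum(pos & outcomes == 0)
  tp / n - (fp / n) * (threshold / (1 - threshold))
}

#' Calibration smoother configuration
#'
#' The default smoother regresses the outcome on a natural cubic spline of
#' the logit of the predicted risk via logistic regression — flexible,
#' stable in the tails and fast enough to fit hundreds of bootstrap
#' curves. `method = "loess"` substitutes a local-linear smoother of the
#' outcome on the risk scale.
#'
#' @param method `"spline"` (logistic on logit risk) or `"loess"`.
#' @param df spline degrees of freedom.
#' @param span loess span (ignored for splines).
#' @param grid_size number of grid points the curve is evaluated on.
#' @param support central probability mass of the predictions defining the
#'   evaluation range (default 0.99: the curve is truncated to the central
#'   99% of the prediction distribution to avoid tail extrapolation).
#' @param min_n minimum number of observations required.
#' @return A list of class `"cal_smoother"`.
#' @export
cal_smoother <- function(method = c("spline", "loess"), df = 4L, span = 0.75,
                         grid_size = 100L, support = 0.99, min_n = 50L) {
  method <- match.arg(method)
  structure(list(method = method, df = as.integer(df), span = span,
                 grid_size = as.integer(grid_size), support = support,
                 min_n = as.integer(min_n)),
            class = "cal_smoother")
}

#' Smoothed calibration curve
#'
#' Estimates the observed event probability as a smooth function of the
#' predicted risk, evaluated on an equally spaced grid over the central
#' support of the predictions. Perfect calibration puts the curve on the
#' diagonal.
#'
#' @param risks predicted risks in (0, 1).
#' @param outcomes binary 0/1 vector, both classes present.
#' @param smoother a [cal_smoother()] configuration.
#' @return An object of class `"calibration_curve"`: list with `grid`
#'   (strictly increasing risk values), `smoothed_observed` (estimated
#'   event probability at each grid point, in \[0, 1\]), `support_range`
#'   and the `smoother` used.
#' @export
calibration_curve <- function(risks, outcomes, smoother = cal_smoother()) {
  stopifnot(inherits(smoother, "cal_smoother"),
            length(risks) == length(outcomes))
  n <- length(risks)
  if (n < smoother$min_n) {
    stop(sprintf("calibration curve needs at least %d observations",
                 smoother$min_n), call. = FALSE)
  }
  if (any(risks <= 0 | risks >= 1)) {
    stop("risks must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2L) {
    stop("degenerate calibration curve: outcome is constant", call. = FALSE)
  }
  support_range <- unname(stats::quantile(
    risks, c((1 - smoother$support) / 2, 1 - (1 - smoother$support) / 2),
    type = 7))
  if (diff(support_range) <= 0) {
    stop("degenerate calibration curve: predictions carry (almost) no spread",
         call. = FALSE)
  }
  grid <- seq(support_range[1], support_range[2],
              length.out = smoother$grid_size)
  if (smoother$method == "spline") {
    lp <- stats::qlogis(risks)
    # fitted values pinned at 0/1 are routine for a flexible smoother in
    # sparse tails and carry no message for the user
    fit <- withCallingHandlers(
      stats::glm(outcomes ~ splines::ns(lp, df = smoother$df),
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    obs <- as.numeric(stats::predict(
      fit, newdata = data.frame(lp = stats::qlogis(grid)), type = "response"))
  } else {
    fit <- stats::loess(outcomes ~ risks, span = smoother$span,
                        degree = 1L,
                        data = data.frame(risks = risks, outcomes = outcomes))
    obs <- as.numeric(stats::predict(fit, newdata = data.frame(risks = grid)))
    obs <- pmin(pmax(obs, 0), 1)
  }
  structure(list(grid = grid, smoothed_observed = obs,
                 support_range = support_range, smoother = smoother),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  dev <- max(abs(x$smoothed_observed - x$grid))
  cat(sprintf(
    "Calibration curve (%s): %d grid points on [%.4f, %.4f], max |obs - pred| = %.4f\n",
    x$smoother$method, length(x$grid), x$support_range[1], x$support_range[2],
    dev))
  invisible(x)
}

#' Evaluate a calibration curve at given predicted risks
#'
#' Linear interpolation between grid points; `NA` outside the curve's
#' support range (no extrapolation).
#' @param curve a [calibration_curve()].
#' @param at risks to evaluate at.
#' @return Numeric vector, `NA` outside `support_range`.
#' @export
eval_curve <- function(curve, at) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- stats::approx(curve$grid, curve$smoothed_observed, xout = at,
                       rule = 1)$y
  out[at < curve$support_range[1] | at > curve$support_range[2]] <- NA_real_
  out
}

#' Write a calibration curve to CSV
#' @param curve a [calibration_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(grid = curve$grid, smoothed_observed = curve$smoothed_observed),
    path, row.names = FALSE)
  invisible(path)
}

#' Events per candidate predictor parameter
#'
#' A coarse sample-size heuristic for binary-outcome prediction models:
#' the number of outcome events divided by the number of candidate
#' predictor parameters.
#'
#' @param n_events number of outcome events.
#' @param n_parameters number of candidate predictor parameters (>= 1).
#' @return The ratio, with attribute `"rounded"` giving its
#'   nearest-integer rounding.
#' @examples
#' events_per_parameter(2851, 8)  # 356.375, rounds to 356
#' @export
events_per_parameter <- function(n_events, n_parameters) {
  if (!is.numeric(n_parameters) || n_parameters < 1) {
    stop("`n_parameters` must be at least 1", call. = FALSE)
  }
  if (!is.numeric(n_events) || n_events < 0) {
    stop("`n_events` must be non-negative", call. = FALSE)
  }
  ratio <- n_events / n_parameters
  structure(ratio, rounded = as.integer(round(ratio)),
            class = "events_per_parameter")
}

#' @export
print.events_per_parameter <- function(x, ...) {
  cat(sprintf("%.4g events per predictor parameter (~%d)\n",
              unclass(x), attr(x, "rounded")))
  invisible(x)
}
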