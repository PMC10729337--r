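# Synthetic cohort generator: a GUSTO-I-like acute-MI cohort with a known
# data-generating logistic model, so instability behaviour can be studied
# with the truth in hand.

#' Specify a synthetic cohort's data-generating model
#'
#' Predictors are drawn independently from per-predictor distributions and
#' the binary outcome from `Bernoulli(expit(intercept + X beta))`. Each
#' generator is either `list(kind = "bernoulli", p = q)` or
#' `list(kind = "normal", mean = m, sd = s, standardize = TRUE/FALSE)`;
#' standardized normals are emitted as `(x - m)/s`, i.e. exactly standard
#' normal, so the true coefficients of continuous predictors are on a
#' per-SD scale comparable with the binary ones.
#'
#' @param n number of participants (at least 2).
#' @param intercept true intercept on the log-odds scale.
#' @param coefficients named numeric vector of true log-odds effects,
#'   one per predictor.
#' @param generators named list of per-predictor distribution specs, names
#'   matching `coefficients`.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return An object of class `"synthetic_spec"`.
#' @seealso [gusto_spec()] for the packaged default, [simulate_cohort()].
#' @export
synthetic_spec <- function(n, intercept, coefficients, generators, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (is.null(names(coefficients)) ||
      !setequal(names(coefficients), names(generators)) ||
      anyDuplicated(names(coefficients))) {
    stop("`coefficients` and `generators` must share a common set of unique names",
         call. = FALSE)
  }
  for (nm in names(generators)) {
    g <- generators[[nm]]
    if (!is.list(g) || is.null(g$kind) ||
        !g$kind %in% c("bernoulli", "normal")) {
      stop(sprintf("generator for '%s' must have kind 'bernoulli' or 'normal'", nm),
           call. = FALSE)
    }
    if (g$kind == "bernoulli") check_scalar_prob(g$p, sprintf("generators$%s$p", nm))
    if (g$kind == "normal" && (!is.numeric(g$sd) || g$sd <= 0)) {
      stop(sprintf("generator for '%s' requests a continuous predictor with non-positive sd", nm),
           call. = FALSE)
    }
  }
  structure(
    list(n = n, intercept = as.numeric(intercept),
         coefficients = coefficients[names(generators)],
         generators = generators, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: n = %d, %d predictors, intercept %.3f, seed %d\n",
              x$n, length(x$coefficients), x$intercept, x$seed))
  print(data.frame(
    predictor = names(x$coefficients),
    kind = vapply(x$generators, `[[`, "", "kind"),
    beta = unname(x$coefficients), row.names = NULL))
  invisible(x)
}

#' Default GUSTO-I-like cohort specification
#'
#' An acute myocardial infarction cohort with eight candidate predictors
#' of 30-day mortality: sex (female), age, hypertension, hypotension,
#' tachycardia, previous MI, ST elevation on ECG, and systolic blood
#' pressure. Binary prevalences are typical of an acute-MI population;
#' age and systolic blood pressure are standardized continuous predictors.
#' The intercept (-3.82) was calibrated once by Monte Carlo so the marginal
#' 30-day mortality is about 7%, and the effect sizes give the true model a
#' c-statistic of about 0.80.
#'
#' @param n number of participants (default 40830, the classic GUSTO-I size).
#' @param seed integer RNG seed.
#' @return A [synthetic_spec()].
#' @examples
#' co <- simulate_cohort(gusto_spec(n = 2000, seed = 7))
#' mean(co$outcome)
#' @export
gusto_spec <- function(n = 40830L, seed = 1L) {
  synthetic_spec(
    n = n,
    intercept = -3.82,
    coefficients = c(sex = 0.4, age = 1.1, hypertension = 0.15,
                     hypotension = 0.7, tachycardia = 0.5, prev_mi = 0.4,
                     st_elevation = 0.35, sysbp = -0.6),
    generators = list(
      sex          = list(kind = "bernoulli", p = 0.25),
      age          = list(kind = "normal", mean = 61, sd = 12, standardize = TRUE),
      hypertension = list(kind = "bernoulli", p = 0.38),
      hypotension  = list(kind = "bernoulli", p = 0.08),
      tachycardia  = list(kind = "bernoulli", p = 0.30),
      prev_mi      = list(kind = "bernoulli", p = 0.17),
      st_elevation = list(kind = "bernoulli", p = 0.37),
      sysbp        = list(kind = "normal", mean = 129, sd = 23, standardize = TRUE)
    ),
    seed = seed)
}

#' Generate a synthetic cohort from a specification
#'
#' @param spec a [synthetic_spec()].
#' @return A [cohort()] with attribute `"truth"`: a list holding the
#'   generating `intercept`, `coefficients` and per-individual true event
#'   `probabilities`, for truth-known testing.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n
  nms <- names(spec$coefficients)
  with_seed(spec$seed, {
    X <- matrix(0, n, length(nms), dimnames = list(NULL, nms))
    kinds <- character(length(nms))
    for (j in seq_along(nms)) {
      g <- spec$generators[[nms[j]]]
      if (g$kind == "bernoulli") {
        X[, j] <- stats::rbinom(n, 1L, g$p)
        kinds[j] <- "binary"
      } else {
        x <- stats::rnorm(n, g$mean, g$sd)
        if (isTRUE(g$standardize)) x <- (x - g$mean) / g$sd
        X[, j] <- x
        kinds[j] <- "continuous"
      }
    }
    p <- stats::plogis(spec$intercept + drop(X %*% spec$coefficients))
    y <- stats::rbinom(n, 1L, p)
    out <- cohort(y, X, predictor_kinds = kinds)
    attr(out, "truth") <- list(intercept = spec$intercept,
                               coefficients = spec$coefficients,
                               probabilities = p)
    out
  })
}

#' Monte-Carlo estimate of the marginal event prevalence implied by a spec
#'
#' @param spec a [synthetic_spec()].
#' @param mc_n Monte-Carlo sample size.
#' @param seed seed for the Monte-Carlo draw (independent of `spec$seed`).
#' @return Estimated marginal `P(outcome = 1)`.
#' @export
implied_prevalence <- function(spec, mc_n = 200000L, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  big <- spec
  big$n <- as.integer(mc_n)
  big$seed <- as.integer(seed)
  mean(attr(simulate_cohort(big), "truth")$probabilities)
}
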