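# Model development as a first-class, replayable object: the instability
# engine must be able to replicate the entire development process —
# including penalty tuning — inside every bootstrap sample.

#' Define a model development procedure
#'
#' A development procedure is a self-contained recipe that turns a cohort
#' into a fitted risk model. It must be deterministic given its seed and
#' hold no state across invocations, so that replaying it on a bootstrap
#' sample replicates the original development exactly.
#'
#' @param fit function `(cohort, seed)` returning a [risk_model()].
#' @param name short label recorded in provenance.
#' @param candidate_predictors optional character vector restricting the
#'   predictors offered to the procedure; `NULL` means all cohort columns.
#' @return An object of class `"development_procedure"`.
#' @seealso [lasso_procedure()], [mle_procedure()], [develop_model()].
#' @export
development_procedure <- function(fit, name, candidate_predictors = NULL) {
  stopifnot(is.function(fit), is.character(name), length(name) == 1L)
  structure(
    list(fit = fit, name = name, candidate_predictors = candidate_predictors),
    class = "development_procedure")
}

#' @export
print.development_procedure <- function(x, ...) {
  cat(sprintf("Development procedure: %s\n", x$name))
  cat(sprintf("Candidate predictors: %s\n",
              if (is.null(x$candidate_predictors)) "all cohort predictors"
              else paste(x$candidate_predictors, collapse = ", ")))
  invisible(x)
}

#' Construct a fitted risk model
#'
#' The container returned by every development procedure: a logistic
#' risk score `expit(intercept + X beta)` with one coefficient per
#' candidate predictor (zero means dropped by the penalty).
#'
#' @param intercept intercept on the log-odds scale.
#' @param coefficients named numeric vector of log-odds coefficients.
#' @param tuning_record list describing how tuning parameters were chosen
#'   (e.g. selected penalty and the cross-validation path).
#' @param n_used,n_events_used size and event count of the fitting sample.
#' @param procedure_name label of the procedure that produced the model.
#' @return An object of class `"risk_model"`.
#' @export
risk_model <- function(intercept, coefficients, tuning_record = list(),
                       n_used = NA_integer_, n_events_used = NA_integer_,
                       procedure_name = "manual") {
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients))) {
    stop("`coefficients` must have unique names", call. = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept),
         coefficients = coefficients,
         tuning_record = tuning_record,
         n_used = as.integer(n_used),
         n_events_used = as.integer(n_events_used),
         procedure_name = procedure_name),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, digits = 4, ...) {
  cat(sprintf("Risk model (%s), fitted on n = %s (%s events)\n",
              x$procedure_name, x$n_used, x$n_events_used))
  print(round(coef(x), digits))
  if (!is.null(x$tuning_record$lambda)) {
    cat(sprintf("Selected penalty lambda = %.6g\n", x$tuning_record$lambda))
  }
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Condition signalled when a development fit degenerates
#' @noRd
fit_error <- function(message, diagnostics = list()) {
  structure(
    class = c("predstab_fit_error", "error", "condition"),
    list(message = message, call = NULL, diagnostics = diagnostics))
}

#' Penalised (lasso) logistic development procedure
#'
#' The packaged default development strategy: logistic regression with an
#' L1 penalty, the penalty chosen by k-fold cross-validation over a
#' log-spaced grid (deviance-minimising lambda). Predictors are
#' standardized internally for penalisation fairness and coefficients are
#' reported back on the original scale. Fold assignment is seeded from the
#' per-fit seed, so tuning is honestly re-run on every invocation — there
#' is no warm-start leakage between bootstrap fits.
#'
#' Two limiting cases of the grid are recognised: a grid containing only 0
#' reduces to the unpenalised maximum-likelihood logistic fit, and a
#' single positive value fixes the penalty (no cross-validation).
#'
#' @param candidate_predictors optional character vector of predictors to
#'   offer the lasso; default all cohort predictors.
#' @param nfolds number of cross-validation folds (default 10).
#' @param lambda optional penalty grid; default lets glmnet build its
#'   log-spaced path.
#' @return A [development_procedure()].
#' @export
lasso_procedure <- function(candidate_predictors = NULL, nfolds = 10L,
                            lambda = NULL) {
  nfolds <- as.integer(nfolds)
  fit <- function(cohort, seed) {
    assert_two_classes(cohort)
    X <- candidate_matrix(cohort, candidate_predictors)
    y <- cohort$outcome
    n <- length(y)
    if (!is.null(lambda) && all(lambda == 0)) {
      return(fit_unpenalised(X, y, "lasso (penalty grid {0})"))
    }
    if (!is.null(lambda) && length(lambda) == 1L) {
      gfit <- suppressWarnings(
        glmnet(X, y, family = "binomial", lambda = lambda,
               standardize = TRUE))
      beta <- drop(as.matrix(stats::coef(gfit, s = lambda)))
      return(risk_model(
        intercept = beta[["(Intercept)"]],
        coefficients = beta[colnames(X)],
        tuning_record = list(tuner = "fixed penalty", lambda = lambda),
        n_used = n, n_events_used = sum(y),
        procedure_name = "lasso"))
    }
    with_seed(seed, {
      foldid <- sample(rep_len(seq_len(nfolds), n))
      cvfit <- cv.glmnet(X, y, family = "binomial", foldid = foldid,
                         lambda = lambda, type.measure = "deviance",
                         standardize = TRUE)
      beta <- drop(as.matrix(stats::coef(cvfit, s = "lambda.min")))
      risk_model(
        intercept = beta[["(Intercept)"]],
        coefficients = beta[colnames(X)],
        tuning_record = list(
          tuner = sprintf("%d-fold CV, deviance-minimising lambda", nfolds),
          lambda = cvfit$lambda.min,
          lambda_grid = cvfit$lambda,
          cv_deviance = cvfit$cvm,
          foldid_seed = seed),
        n_used = n, n_events_used = sum(y),
        procedure_name = "lasso")
    })
  }
  development_procedure(fit, "lasso", candidate_predictors)
}

#' Unpenalised maximum-likelihood logistic development procedure
#'
#' Plain logistic regression on the full candidate set — the simplest
#' development strategy, useful both in its own right and as a fast
#' procedure for exercising the bootstrap engine.
#'
#' @inheritParams lasso_procedure
#' @return A [development_procedure()].
#' @export
mle_procedure <- function(candidate_predictors = NULL) {
  fit <- function(cohort, seed) {
    assert_two_classes(cohort)
    X <- candidate_matrix(cohort, candidate_predictors)
    fit_unpenalised(X, cohort$outcome, "mle")
  }
  development_procedure(fit, "mle", candidate_predictors)
}

candidate_matrix <- function(cohort, candidate_predictors) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(candidate_predictors)) return(cohort$predictors)
  missing_cols <- setdiff(candidate_predictors, colnames(cohort$predictors))
  if (length(missing_cols)) {
    stop(sprintf("candidate predictor(s) absent from cohort: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cohort$predictors[, candidate_predictors, drop = FALSE]
}

fit_unpenalised <- function(X, y, label) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  gf <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        stop(fit_error(
          sprintf("degenerate %s fit: %s", label, conditionMessage(w)),
          diagnostics = list(n = length(y), events = sum(y))))
      }
      invokeRestart("muffleWarning")
    })
  if (!gf$converged) {
    stop(fit_error(sprintf("%s fit did not converge", label),
                   diagnostics = list(n = length(y), events = sum(y))))
  }
  beta <- stats::coef(gf)
  risk_model(
    intercept = beta[["(Intercept)"]],
    coefficients = stats::setNames(beta[-1L], colnames(X)),
    tuning_record = list(tuner = label, lambda = 0),
    n_used = length(y), n_events_used = sum(y),
    procedure_name = label)
}

#' Develop a risk model on a cohort
#'
#' Runs a development procedure end to end — including any tuning — on the
#' cohort. Deterministic given `seed`; running it twice with the same seed
#' yields bitwise-identical models.
#'
#' @param cohort a [cohort()] with both outcome classes present.
#' @param procedure a [development_procedure()].
#' @param seed integer seed for any randomness inside the procedure
#'   (e.g. cross-validation fold assignment).
#' @return A [risk_model()].
#' @examples
#' co <- simulate_cohort(gusto_spec(n = 1500, seed = 3))
#' m <- develop_model(co, lasso_procedure(), seed = 11)
#' m
#' @export
develop_model <- function(cohort, procedure, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(procedure, "development_procedure"))
  assert_two_classes(cohort)
  procedure$fit(cohort, as.integer(seed))
}

#' Predict individual risks from a fitted model
#'
#' @param model a [risk_model()].
#' @param cohort a [cohort()] whose predictors include, by name, every
#'   model coefficient.
#' @return Numeric vector of predicted event probabilities in (0, 1),
#'   one per cohort row.
#' @export
predict_risks <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"), inherits(cohort, "cohort"))
  nms <- names(model$coefficients)
  missing_cols <- setdiff(nms, colnames(cohort$predictors))
  if (length(missing_cols)) {
    stop(sprintf("cohort lacks predictor(s) required by the model: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- cohort$predictors[, nms, drop = FALSE]
  stats::plogis(model$intercept + drop(X %*% model$coefficients))
}

#' @export
predict.risk_model <- function(object, newdata, ...) {
  if (inherits(newdata, "cohort")) return(predict_risks(object, newdata))
  predict_risks(object, cohort(rep(0, nrow(as.matrix(newdata))),
                               as.matrix(newdata)))
}

#' Write a fitted risk model to JSON
#' @param model a [risk_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         tuning_record = model$tuning_record[
           setdiff(names(model$tuning_record), c("lambda_grid", "cv_deviance"))],
         n_used = model$n_used, n_events_used = model$n_events_used,
         procedure_name = model$procedure_name),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted risk model from JSON
#' @param path path written by [write_model()].
#' @return A [risk_model()].
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(x$intercept, unlist(x$coefficients),
             tuning_record = as.list(x$tuning_record),
             n_used = x$n_used, n_events_used = x$n_events_used,
             procedure_name = x$procedure_name)
}
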