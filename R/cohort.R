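# Cohort container: outcome vector + predictor matrix, with CSV I/O.

#' Construct a development cohort
#'
#' A cohort bundles a binary outcome (1 = event, e.g. 30-day death), an
#' n x p numeric predictor matrix and row identifiers. It is the unit of
#' data that a development procedure consumes and that the bootstrap
#' instability engine resamples.
#'
#' @param outcome numeric or integer vector of 0/1 outcomes, length n.
#' @param predictors numeric matrix (or data frame coercible to one) with
#'   named columns, n rows.
#' @param ids optional vector of unique row identifiers; defaults to `1:n`.
#' @param predictor_kinds optional character vector (`"binary"` or
#'   `"continuous"`), one per predictor. Inferred when omitted: a column
#'   with at most two distinct values is binary.
#'
#' @return An object of class `"cohort"`: a list with elements `ids`,
#'   `outcome`, `predictors`, `predictor_kinds`.
#' @examples
#' X <- cbind(age = rnorm(20), smoker = rbinom(20, 1, 0.3))
#' co <- cohort(rbinom(20, 1, 0.4), X)
#' co
#' @export
cohort <- function(outcome, predictors, ids = NULL, predictor_kinds = NULL) {
  predictors <- as.matrix(predictors)
  if (!is.numeric(predictors)) {
    stop("`predictors` must be numeric", call. = FALSE)
  }
  if (is.null(colnames(predictors)) || anyDuplicated(colnames(predictors))) {
    stop("`predictors` must have unique column names", call. = FALSE)
  }
  n <- length(outcome)
  if (nrow(predictors) != n) {
    stop(sprintf("outcome has length %d but predictors has %d rows",
                 n, nrow(predictors)), call. = FALSE)
  }
  if (n < 1L) stop("cohort must contain at least one row", call. = FALSE)
  if (anyNA(outcome) || anyNA(predictors)) {
    bad <- which(is.na(outcome) | rowSums(is.na(predictors)) > 0)
    stop(sprintf(
      "missing values are not allowed; offending rows: %s",
      paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  outcome <- as.numeric(outcome)
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome must contain only 0 and 1", call. = FALSE)
  }
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n || anyDuplicated(ids)) {
    stop("`ids` must be unique and of length n", call. = FALSE)
  }
  if (is.null(predictor_kinds)) {
    predictor_kinds <- apply(predictors, 2L, function(x) {
      if (length(unique(x)) <= 2L) "binary" else "continuous"
    })
  }
  predictor_kinds <- as.character(predictor_kinds)
  if (length(predictor_kinds) != ncol(predictors) ||
      !all(predictor_kinds %in% c("binary", "continuous"))) {
    stop("`predictor_kinds` must be 'binary' or 'continuous', one per predictor",
         call. = FALSE)
  }
  names(predictor_kinds) <- colnames(predictors)
  structure(
    list(ids = ids, outcome = outcome, predictors = predictors,
         predictor_kinds = predictor_kinds),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$outcome)
  ev <- sum(x$outcome)
  cat(sprintf("Cohort: %d participants, %d events (%.1f%%)\n",
              n, ev, 100 * ev / n))
  cat(sprintf("Predictors (%d): %s\n", ncol(x$predictors),
              paste(sprintf("%s [%s]", colnames(x$predictors),
                            substr(x$predictor_kinds, 1, 4)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(id = x$ids, outcome = x$outcome, x$predictors,
             check.names = FALSE)
}

#' @export
dim.cohort <- function(x) c(length(x$outcome), ncol(x$predictors))

#' Number of outcome events in a cohort
#' @param cohort a [cohort()] object.
#' @return integer event count.
#' @export
n_events <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  as.integer(sum(cohort$outcome))
}

assert_two_classes <- function(cohort, what = "model development") {
  ev <- sum(cohort$outcome)
  if (ev == 0 || ev == length(cohort$outcome)) {
    stop(sprintf("cohort has a single outcome class; %s requires both events and non-events",
                 what), call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort from a CSV file
#'
#' Loads a rectangular CSV with a header row, picks out the outcome and
#' predictor columns by name and validates the result. Missing cells are
#' rejected (no silent imputation): the development procedure presumes a
#' complete dataset.
#'
#' @param path path to a CSV file (UTF-8, '.' decimal separator).
#' @param outcome_name name of the binary outcome column.
#' @param predictor_names character vector of predictor column names;
#'   defaults to every column except the outcome and any `id` column.
#' @param id_name optional name of an identifier column.
#' @return A [cohort()].
#' @export
read_cohort <- function(path, outcome_name, predictor_names = NULL,
                        id_name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  have <- names(df)
  want <- c(outcome_name, predictor_names, id_name)
  missing_cols <- setdiff(want, have)
  if (length(missing_cols)) {
    stop(sprintf("column(s) not present in %s: %s (available: %s)",
                 path, paste(missing_cols, collapse = ", "),
                 paste(have, collapse = ", ")), call. = FALSE)
  }
  if (is.null(predictor_names)) {
    predictor_names <- setdiff(have, c(outcome_name, id_name, "id"))
  }
  out <- df[[outcome_name]]
  if (anyNA(out) || !all(out %in% c(0, 1))) {
    bad <- which(is.na(out) | !(out %in% c(0, 1)))
    stop(sprintf("outcome column '%s' must be 0/1; offending rows: %s",
                 outcome_name, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  X <- df[predictor_names]
  non_num <- predictor_names[!vapply(X, is.numeric, logical(1))]
  if (length(non_num)) {
    stop(sprintf("predictor column(s) not numeric: %s",
                 paste(non_num, collapse = ", ")), call. = FALSE)
  }
  ids <- if (!is.null(id_name)) df[[id_name]]
         else if ("id" %in% have) df[["id"]]
         else NULL
  cohort(out, as.matrix(X), ids = ids)
}

#' Write a cohort to a CSV file
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the cohort exactly. A sidecar JSON file records
#' the predictor kinds and any provenance supplied.
#'
#' @param cohort a [cohort()].
#' @param path output CSV path.
#' @param metadata optional named list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, metadata = list()) {
  stopifnot(inherits(cohort, "cohort"))
  df <- as.data.frame(cohort)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(outcome = "outcome",
                 predictors = colnames(cohort$predictors),
                 predictor_kinds = as.list(cohort$predictor_kinds)),
            metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Draw a random sub-sample of a cohort
#'
#' Simple random sampling without replacement, used to emulate the common
#' situation where only a fraction of the target population's data is
#' available for model development. If the draw leaves a single outcome
#' class (and the parent cohort has both), it is redrawn with a fresh
#' derived seed; the redraw count is recorded in `attr(., "redraws")`.
#'
#' @param cohort a [cohort()].
#' @param m sub-sample size, `2 <= m <= n`.
#' @param seed integer seed; the draw is deterministic given it.
#' @param exact_events optional integer: condition the draw on exactly this
#'   many events (stratified draw), for reproducing a stated event count.
#' @param max_redraws redraw cap before giving up.
#' @return A [cohort()] of `m` rows with attribute `"redraws"`.
#' @export
subsample_cohort <- function(cohort, m, seed, exact_events = NULL,
                             max_redraws = 50L) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$outcome)
  m <- as.integer(m)
  if (m < 2L || m > n) {
    stop(sprintf("`m` must be between 2 and n = %d", n), call. = FALSE)
  }
  seeds <- derive_seeds(seed, max_redraws + 1L)
  if (!is.null(exact_events)) {
    exact_events <- as.integer(exact_events)
    ev_idx <- which(cohort$outcome == 1)
    nev_idx <- which(cohort$outcome == 0)
    if (exact_events > length(ev_idx) || m - exact_events > length(nev_idx)) {
      stop("`exact_events` not attainable from this cohort", call. = FALSE)
    }
    idx <- with_seed(seeds[1L], {
      c(sample(ev_idx, exact_events), sample(nev_idx, m - exact_events))
    })
    idx <- sort(idx)
    redraws <- 0L
  } else {
    both <- length(unique(cohort$outcome)) == 2L
    redraws <- 0L
    repeat {
      idx <- with_seed(seeds[redraws + 1L], sort(sample.int(n, m)))
      y <- cohort$outcome[idx]
      if (!both || length(unique(y)) == 2L) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("sub-sample redraw cap exceeded: could not obtain both outcome classes",
             call. = FALSE)
      }
    }
  }
  out <- cohort(cohort$outcome[idx],
                cohort$predictors[idx, , drop = FALSE],
                ids = cohort$ids[idx],
                predictor_kinds = cohort$predictor_kinds)
  attr(out, "redraws") <- redraws
  out
}

#' Select rows of a cohort by index
#' @noRd
cohort_rows <- function(cohort, idx, reset_ids = TRUE) {
  structure(
    list(ids = if (reset_ids) seq_along(idx) else cohort$ids[idx],
         outcome = cohort$outcome[idx],
         predictors = cohort$predictors[idx, , drop = FALSE],
         predictor_kinds = cohort$predictor_kinds),
    class = "cohort")
}
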