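# Optional fetcher for the real GUSTO-I trial data (hbiostat.org), mapped
# to the eight-predictor 30-day mortality setup. Network-dependent; never
# required by the test suite.

#' Default mapping from GUSTO-I columns to the eight-predictor setup
#'
#' The distributed dataset does not label hypotension or tachycardia
#' directly; conventional clinical cut-offs are applied (systolic blood
#' pressure < 100 mmHg, pulse > 80 bpm). Every entry can be overridden;
#' each is either a column name or a function of the loaded data frame
#' returning a numeric vector.
#'
#' @return Named list of column mappings.
#' @export
gusto_mapping <- function() {
  list(
    outcome      = "day30",
    sex          = function(d) as.numeric(d$sex == "female"),
    age          = "age",
    hypertension = function(d) as.numeric(d$htn == "yes" | d$htn == 1),
    hypotension  = function(d) as.numeric(d$sysbp < 100),
    tachycardia  = function(d) as.numeric(d$pulse > 80),
    prev_mi      = function(d) as.numeric(d$pmi == "yes" | d$pmi == 1),
    st_elevation = function(d) as.numeric(d$ste == "yes" | d$ste == 1),
    sysbp        = "sysbp"
  )
}

#' Fetch the GUSTO-I dataset and map it to a cohort
#'
#' Downloads `gusto.rda` from hbiostat.org (cached in `cache_dir`, so later
#' calls work offline), loads it and assembles the 30-day mortality cohort
#' with the eight standard predictors. The applied column mapping is
#' recorded in `attr(., "mapping")` since part of it rests on clinical
#' cut-off conventions rather than labelled source columns.
#'
#' @param cache_dir directory for the cached `.rda` file.
#' @param mapping a mapping list as produced by [gusto_mapping()]; override
#'   entries to change column derivations.
#' @param url source URL of the `.rda` file.
#' @return A [cohort()] with attribute `"mapping"`.
#' @export
fetch_gusto <- function(cache_dir = tools::R_user_dir("predstab", "cache"),
                        mapping = gusto_mapping(),
                        url = "https://hbiostat.org/data/gusto.rda") {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- file.path(cache_dir, "gusto.rda")
  if (!file.exists(dest)) {
    ok <- tryCatch(utils::download.file(url, dest, mode = "wb", quiet = TRUE),
                   error = function(e) -1L, warning = function(w) -1L)
    if (!identical(ok, 0L)) {
      if (file.exists(dest)) unlink(dest)
      stop(sprintf(paste0(
        "could not download GUSTO-I data from %s; ",
        "check network access and retry, or place gusto.rda in %s"),
        url, cache_dir), call. = FALSE)
    }
  }
  env <- new.env()
  load(dest, envir = env)
  obj <- ls(env)[1]
  d <- get(obj, envir = env)
  cols <- lapply(names(mapping), function(nm) {
    m <- mapping[[nm]]
    v <- if (is.function(m)) {
      tryCatch(m(d), error = function(e) NULL)
    } else if (m %in% names(d)) {
      d[[m]]
    } else NULL
    if (is.null(v) || anyNA(v)) {
      stop(sprintf(
        "could not derive '%s' from the GUSTO-I table (available columns: %s); override `mapping`",
        nm, paste(names(d), collapse = ", ")), call. = FALSE)
    }
    as.numeric(v)
  })
  names(cols) <- names(mapping)
  out <- cohort(cols$outcome,
                do.call(cbind, cols[setdiff(names(cols), "outcome")]))
  attr(out, "mapping") <- mapping
  out
}
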