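# RNG plumbing: one master seed per run, child seeds derived deterministically.

#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive `n` child seeds from a master seed
#'
#' Child seeds are drawn without replacement from 1..(2^31 - 2) under the
#' master seed, so every downstream consumer (generation, subsampling, each
#' bootstrap column, each model fit) gets an independent, reproducible stream.
#' @noRd
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  with_seed(as.integer(seed), sample.int(2147483646L, n))
}

check_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop(sprintf("`%s` must be a single number in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}
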