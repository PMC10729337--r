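# Brute-force oracles, deliberately written as naive loops over the
# definitions so they stay independent of the package's vectorised paths.

oracle_cstat <- function(risks, outcomes) {
  num <- 0
  for (i in which(outcomes == 1)) {
    for (j in which(outcomes == 0)) {
      num <- num + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
    }
  }
  num / (sum(outcomes == 1) * sum(outcomes == 0))
}

oracle_mape <- function(p, M) {
  B <- ncol(M)
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    errs <- numeric(B)
    for (b in seq_len(B)) errs[b] <- abs(M[i, b] - p[i])
    out[i] <- sum(errs) / B
  }
  out
}

oracle_cii <- function(p, M, t) {
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    cnt <- 0
    for (b in seq_len(ncol(M))) {
      cnt <- cnt + ((M[i, b] >= t) != (p[i] >= t))
    }
    out[i] <- cnt / ncol(M)
  }
  out
}

# linear interpolation between order statistics, at the 1-based index
# j + g = 1 + (n-1) q:  Q(q) = (1-g) x_(j) + g x_(j+1)
oracle_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  idx <- 1 + (n - 1) * q
  lo <- floor(idx)
  g <- idx - lo
  (1 - g) * xs[lo] + g * xs[min(lo + 1, n)]
}

oracle_net_benefit <- function(risks, outcomes, t) {
  n <- length(risks)
  tp <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (risks[i] >= t) {
      if (outcomes[i] == 1) tp <- tp + 1 else fp <- fp + 1
    }
  }
  tp / n - (fp / n) * (t / (1 - t))
}

# assemble a bootstrap_predictions object directly from a prediction
# vector and a multiverse matrix, for desk-checking the summaries
make_preds <- function(p, M) {
  structure(
    list(original = p, multiverse = M, B = ncol(M),
         model = NULL,
         provenance = list(seed = 0L, procedure = "manual", n = length(p),
                           redraws = 0L, failures = character(0))),
    class = "bootstrap_predictions")
}

toy_cohort <- function(n = 120, seed = 1, p_event = 0.35) {
  with_seed_env(seed, {
    x1 <- rnorm(n)
    x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(qlogis(p_event) + 0.8 * x1 + 0.5 * x2))
    cohort(y, cbind(x1 = x1, x2 = x2))
  })
}

with_seed_env <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

constant_procedure <- function(model) {
  development_procedure(function(cohort, seed) model, "constant")
}
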