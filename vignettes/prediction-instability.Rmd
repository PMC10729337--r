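---
title: "Assessing the instability of individual risk predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the instability of individual risk predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predstab)
```

## The problem

A clinical prediction model maps an individual's predictor values to an
estimated outcome risk — say, 30-day mortality after an acute myocardial
infarction. The model that gets published is the product of one
development dataset of size $n$ drawn from the target population. Had a
different sample of the same size been drawn, the *same* development
process (same candidate predictors, same penalty tuning) would have
produced a different model — different selected predictors, different
coefficients — and, crucially, possibly a very different predicted risk
for the same individual. The collection of models that could have arisen
this way is the model's *multiverse*, and the variability of an
individual's prediction across it is *instability*: epistemic
(reducible) uncertainty created by the model-production process itself,
distinct from the aleatoric outcome noise that no model removes.

Instability matters clinically because single predicted values drive
counselling, resource prioritisation and treatment thresholds. If half
the multiverse puts a patient above a 10% statin-initiation threshold
and half below, the published model's classification of that patient
deserves little confidence — however good its c-statistic looks.

## The bootstrap procedure

`predstab` approximates the multiverse by bootstrap resampling of the
development cohort:

1. develop the model on the original cohort and record each individual's
   prediction $\hat p_i$;
2. draw a bootstrap sample of size $n$ with replacement;
3. re-run the *entire* development process on it — including
   cross-validated penalty tuning, with a fresh fold assignment;
4. apply the resulting model to the original cohort, giving
   $\hat p_{bi}$;
5. repeat for $b = 1, \dots, B$ (default $B = 200$; fewer than 200
   triggers a warning);
6. summarise, per individual and across the cohort.

The per-individual summaries are the mean absolute prediction error

$$\mathrm{MAPE}_i = \frac{1}{B} \sum_{b=1}^{B} \lvert \hat p_{bi} - \hat p_i \rvert,$$

percentile instability intervals (2.5th/97.5th of the $B$ predictions by
default), and the classification instability index at a decision
threshold $t$:

$$\mathrm{CII}_i(t) = \frac{1}{B} \sum_{b=1}^{B}
  \mathbf{1}\left[\,\mathbf{1}(\hat p_{bi} \ge t) \ne \mathbf{1}(\hat p_i \ge t)\,\right],$$

the estimated probability that an alternative model from the multiverse
would classify the individual differently from the original model. At
the model level, the c-statistic, net benefit
($\mathrm{TP}/n - (\mathrm{FP}/n)\, t/(1-t)$) and a smoothed calibration
curve are computed for every bootstrap model applied to the original
cohort; their spread across $b$ is the discrimination, clinical-utility
and calibration instability.

```{r example, eval = FALSE}
co <- simulate_cohort(gusto_spec(n = 2000, seed = 7))
rep <- instability(co, lasso_procedure(), B = 200, seed = 7,
                   thresholds = 0.1)
summary(rep)
plot(rep, "prediction")
plot(rep, "classification")
plot(rep, "calibration")
```

## Conventions and numerical choices

* **Classification**: a risk at or above the threshold is positive; ties
  at the threshold classify positive. One convention is fixed because
  "above 10%" and "at least 0.1" are used interchangeably in practice.
* **Percentiles**: empirical quantiles with linear interpolation between
  order statistics at index $1 + (n-1)p$ (`stats::quantile` type 7),
  used identically for instability intervals, c-statistic and
  net-benefit spreads, and MAPE summaries.
* **MAPE arithmetic**: computed as a row sum of absolute errors divided
  by $B$, so the result is bit-for-bit what the defining sum gives in
  double precision.
* **Calibration smoother**: logistic regression of the outcome on a
  natural cubic spline (4 df) of the logit of the predicted risk,
  evaluated on a 100-point grid over the central 99% of the prediction
  distribution. The spline-on-logit form is stable in the tails and
  cheap enough to fit hundreds of bootstrap curves; a loess alternative
  is available via `cal_smoother(method = "loess")`. Curves are never
  evaluated outside their support range, and the truncation to the
  central 99% avoids tail extrapolation artefacts in overlays. With
  predictions that are self-consistent (outcomes simulated from the
  predictions themselves), the fitted curve sits within 0.02 of the
  diagonal at $n = 10^5$.
* **Degenerate resamples**: a bootstrap sample with a single outcome
  class, or one on which the development fit degenerates (separation,
  non-convergence), is redrawn with a fresh derived seed. Redraws are
  logged in the provenance and capped at 50 per run; exceeding the cap
  aborts with advice that the cohort is too small for a stable
  assessment. Dropping such columns would silently bias $B$ downward,
  and accepting them would crash or distort fits.
* **Seeds**: one master seed per run. Child seeds for generation,
  sub-sampling, the original fit, every bootstrap draw and every
  bootstrap refit are pre-derived from it, so the whole report is
  reproducible bitwise and would be unchanged under any execution
  order of the columns. The multiverse matrix is materialised in full
  (about 163 MB for $40{,}830 \times 500$ doubles), which modern
  machines absorb comfortably; no streaming mode is provided.

## The development procedure as an object

Step 3 only exposes real instability if the bootstrap replays *exactly*
what was done originally. `development_procedure()` therefore makes the
development process a first-class value: a self-contained function from
a cohort (plus seed) to a fitted `risk_model`, with no state shared
across invocations. The packaged default, `lasso_procedure()`, is
penalised logistic regression with the L1 penalty chosen by 10-fold
cross-validation over a log-spaced grid, minimising binomial deviance.
Predictors are standardized internally for penalisation fairness and
coefficients reported on the original scale. The tuning scheme is
recorded in the model's `tuning_record`, since "a lasso" underdetermines
the development process — different fold schemes give (slightly)
different multiverses. Two limiting cases are honoured: a penalty grid
of `{0}` is the plain maximum-likelihood fit, and a single positive
penalty is fitted without cross-validation. `mle_procedure()` ships as
the unpenalised alternative, and users can register anything else
(elastic net, trees, ...) through `development_procedure()`; whether the
engine's re-tuning honestly reflects the original development is then
the user's responsibility.

The engine re-tunes the penalty inside every bootstrap sample. If the
original development froze its penalty before bootstrapping, its
instability would be understated relative to what this package reports;
that choice is recorded in each model's tuning record.

## The synthetic cohort

`gusto_spec()` emulates a large acute-MI trial cohort: eight candidate
predictors of 30-day mortality — sex (female), age, hypertension,
hypotension, tachycardia, previous MI, ST elevation on ECG, systolic
blood pressure — with binary prevalences 0.25, 0.38, 0.08, 0.30, 0.17,
0.37 typical of such a population, and age and systolic blood pressure
standard-normal after population standardization (so all true effects
are on a comparable per-SD / per-category log-odds scale). The true
effects (0.4, 1.1, 0.15, 0.7, 0.5, 0.4, 0.35, −0.6) and the
Monte-Carlo-calibrated intercept (−3.82) were chosen once so the
marginal mortality is about 7% and the true model's c-statistic about
0.80, matching the epidemiology of the motivating setting; they are
frozen as package defaults.

What the generator deliberately does *not* emulate: correlation between
predictors (real age and blood pressure are dependent), non-linear or
interaction effects, measurement error, and missingness. Passing tests
on this cohort therefore demonstrate that the machinery is correct and
that the sample-size mechanics of instability behave as theory predicts
— not that any particular real dataset is stable. Missing data are
rejected at load time rather than imputed, because the bootstrap
replays a complete-data development process; imputation-in-the-bootstrap
is a possible extension, not implemented.

## Sample size and instability

The central empirical fact the package exposes: instability shrinks
roughly with $\sqrt{n}$, and small development samples produce
individually meaningless predictions long after headline discrimination
looks fine. On the synthetic cohort, the full-scale analysis
($n = 40{,}830$, $B = 200$) gives mean MAPE near 0.003, while a
500-participant sub-sample (about 35 events, roughly 4 events per
predictor parameter) gives mean MAPE an order of magnitude larger with
individual instability intervals spanning most of the risk scale — yet
its c-statistic spread stays narrow, because the c-statistic is a
cohort-level average that instability largely cancels out of.
`learning_curve()` tracks mean/max MAPE over increasing development
sizes to indicate how much more data would be needed; `subgroup_mape()`
breaks MAPE down by subgroup, where under-represented groups routinely
show worse instability — a fairness concern invisible in aggregate
metrics.

Problem sizes used by the shipped checks: the test suite exercises the
engine at $n \le 2000$, $B \le 100$ (ten paired replicates for the
sample-size contrast), with the larger $n = 10^5$ reserved for the
calibration self-consistency and prevalence-convergence properties;
`scripts/acceptance.R` runs the full $n = 40{,}830$ and $n = 500$
analyses at $B = 200$ without the calibration-curve bundle, which the
headline numbers do not need.

## Real data

`fetch_gusto()` downloads and caches the public GUSTO-I dataset and maps
it to this eight-predictor setup. Two of the predictors (hypotension,
tachycardia) are not labelled columns in the distributed table and are
derived by conventional clinical cut-offs (systolic blood pressure
< 100 mmHg, pulse > 80 bpm); the mapping is recorded on the returned
cohort and overridable via `gusto_mapping()`. Together with the
unrecorded tuning scheme of the published analysis, this means
real-data summary numbers are reproduced in distribution rather than
digit-for-digit. `scripts/reproduce_gusto.R` runs the full $B = 500$
real-data analysis when network access is available.

## Known limitations

Only binary outcomes are supported (no survival or continuous
outcomes). The bootstrap reflects instability with respect to the
original target population only — transportability to other settings is
external validation, a different question. Bootstrap samples from small
or unrepresentative cohorts can *understate* true population
instability. And the multiverse explored is the one induced by sampling
variability under a fixed development strategy; variability across
modelling strategies ("researcher degrees of freedom") is deliberately
out of scope.
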