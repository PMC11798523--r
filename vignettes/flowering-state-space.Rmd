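---
title: "Estimating true flowering dates with a time-varying-coefficient state-space model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating true flowering dates with a time-varying-coefficient state-space model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Long cherry-flowering records are a classic probe of how spring phenology
responds to climate, but real records are short, sparse and noisy: a
famous tree may have daily website reports since 1989, scattered dates in
local literature and private photo collections before that, and nothing at
all for most of the twentieth century. Observed dates also carry error —
visual inspection, observer differences, microclimate. `hanami` treats the
*true* date of each phenophase (first flowering FFL, first full bloom FFB,
last full bloom LFB, last flowering LFL) as a latent quantity and
estimates its full posterior distribution for every year of a century,
driven only by coarse seasonal air-temperature summaries from a nearby
weather station.

## The model

For each phenophase independently, with years $t = 1, \dots, n$:

* **FFL / FFB form** (two predictors). The true date (in day of year) is
  $$\alpha_t = \mu_t + \beta_t\,ex1_t + \gamma_t\,ex2_t,$$
  where $ex1_t$ is the mean daily *minimum* temperature from 1 December of
  year $t-1$ to 28/29 February of year $t$ (winter chilling that releases
  bud endodormancy) and $ex2_t$ the mean daily temperature over 1–31 March
  (heat forcing of bud growth).
* **LFB / LFL form** (one predictor).
  $$\alpha_t = \mu_t + \beta_t\,ex3_t,$$
  with $ex3_t$ the mean daily temperature over 1–10 April (heat forcing of
  late flower and leaf growth).

Intercept and coefficients evolve as independent Gaussian random walks,
$$\mu_t = \mu_{t-1} + \omega_t,\quad
  \beta_t = \beta_{t-1} + \tau_t,\quad
  \gamma_t = \gamma_{t-1} + \upsilon_t,$$
with $\omega_t \sim N(0, \sigma_\omega^2)$ and so on, which lets the
temperature sensitivity itself drift over decades instead of being a fixed
regression constant. An observed date, where one exists, is the true date
plus white noise:
$$y_t = \alpha_t + \varphi_t,\qquad \varphi_t \sim N(0, \sigma_\varphi^2).$$
Years without a record contribute no observation term; the random walks
simply propagate, which is exactly what lets the model cover record-free
decades — at the cost of credible intervals that widen the further one
extrapolates from data.

## Priors and their defaults

* **Initial states** $\mu_0, \beta_0, \gamma_0$: diffuse
  $N(0, 100^2)$ (days, days/°C), a proper approximation of a flat prior.
  The same value initialises the exact Kalman recursions so the two
  inference routes answer the identical question.
* **SD parameters** $\sigma_\omega, \sigma_\tau, \sigma_\upsilon,
  \sigma_\varphi$: half-normal with scale 10 days by default
  (`prior_config(sigma_scale = 10)`), or improper flat-on-positive
  (`sigma_prior = "flat"`). The half-normal default is weakly informative;
  with a single observation per year and half the century unobserved, the
  walk SDs are weakly identified, and a proper prior keeps the posterior
  well behaved over long unobserved stretches.

## Inference

`sample_posterior()` runs a Gibbs sampler that alternates

1. an **exact forward-filter backward-sampling** (FFBS) draw of the entire
   latent state path given the SDs — a single multivariate draw, so the
   states never random-walk through the sampler themselves; and
2. **slice-sampling** updates (stepping-out, on $\log\sigma$) of each SD
   given the states.

With the SDs held fixed the model is linear-Gaussian and
`kalman_smoother()` returns the exact per-year posterior means and SDs;
the test suite requires the MCMC means to agree with both the smoother and
an independent dense joint-Gaussian conditioning oracle within Monte-Carlo
error. Defaults are 4 chains × 5000 iterations, 1000 burn-in, thinning 2
(2000 retained per chain); any scale can be requested, including
full-scale runs of hundreds of thousands of iterations. Split-$\hat R$ (threshold
1.05, warned, never silenced) and autocorrelation-based effective sample
sizes are attached to every fit. The walk SDs mix the slowest; a fit whose
$\hat R$ warns should simply be run longer.

Numerical choices worth knowing:

* Credible intervals are central 2.5 %/97.5 % linear-interpolation
  quantiles (R type 7) of the pooled retained draws.
* Backward-sampling covariances get a relative jitter ($10^{-10}$ of the
  largest diagonal entry) before Cholesky, with an eigenvalue-clipping
  fallback; the diffuse initial variance makes the smoothing subtractions
  cancel to about eight significant digits.
* Pooled coefficient summaries are reported in two labelled flavours:
  `pooled` (median/SD across all years and draws) and `time_averaged`
  (median/SD over draws of each draw's across-year mean). The two agree
  when the paths are nearly constant and diverge when they drift.

## Predictors and data handling

`compute_predictors()` averages only the *present* daily values in each
window and marks a predictor missing when more than 10 % of its days are
missing (configurable). The winter window belongs to the flowering year:
its length is 90 or 91 days according to that year's February, and it
reads December of the previous calendar year. A "monthly mean March
temperature" is implemented as the mean of daily means over 1–31 March.
Readers never impute: blank temperature cells stay missing all the way to
the predictor layer, and implausible values (outside ±50 °C) or malformed
dates are errors that name the offending row.

When several sources report the same year and phenophase, the fitting
layer keeps one value per year by a configurable precedence —
website > municipal > private > literature > photograph — reflecting that
contemporaneous daily website reports are the primary record and
recovered historical records the validation set. An observation mask lets
the user drop year ranges entirely (for instance an era when the tree's
vigour, not the climate, controlled flowering) without touching the state
equations.

## The synthetic-data generator

Because the original station exports and municipal records are external,
`simulate_dataset()` generates datasets from the model's own generative
process, and `default_study_config()` fixes the study conditions:

* years 1924–2024; observations every year from 1989 (FFL/FFB/LFB) or
  2002 (LFL), rounded to integer day of year;
* predictor climatology: winter minimum 1.2 °C (SD 0.8), March mean
  8.0 °C (SD 1.0), early-April mean 13.0 °C (SD 1.3) — mid-latitude
  valley-station values — warming at 0.30/0.25/0.25 °C per decade,
  centred on 2006 so the observed window sits at the modern normal;
* initial coefficients near −3.1 days/°C (winter) and −3.75 days/°C
  (March), with the intercept derived so the observed-window mean date
  lands on the recorded phenophase means (DOY 92.0/96.9/102.1/106.3);
* process SDs 0.3 (intercept), 0.02, 0.05 days/yr (coefficients): the
  sensitivity drifts on decadal scales but does not wander by weeks; and
  observation SD 2.5 days.

The generator emulates the *structure* of real records — late-onset
coverage, integer dates, additive noise, warming-driven advance — but not
everything about real data: no serially correlated observation errors, no
observer changes, no biological regime shifts (a tree's low-vigour era
violates the temperature-driven model and must be masked, not modelled),
and a single station rather than a microclimate. Passing the recovery
tests therefore shows the machinery is correct and calibrated under the
model's own assumptions, not that the model is true of any particular
tree. A `predictor_mode = "daily"` option generates a daily weather
series and pushes it through `compute_predictors()`, exercising the full
temperature-to-posterior path.

## Downstream analyses

`fit_trend()` regresses per-year posterior medians on year by OLS and
reports the slope ×10 as days/decade (an *advance* when negative),
$R^2$ and the two-sided $t$-test p-value; a draw-wise trend distribution
is easy to assemble from `write_draws_csv()` output but the median-based
trend is the primary, classical summary. `coverage_fraction()` measures
how many observed dates fall inside the 95 % band. `compare_stations()`
contrasts two fits of the same phenophase driven by different temperature
stations: an additive temperature offset between stations is absorbed by
the intercept while the estimated true dates and their trends stay put —
the reason a station 29 km away works almost as well as one 1 km away.

## Test and replication scale

The shipped tests and the acceptance script run the full 101-year model
at 4 chains × 2000 retained draws (single fits) and at 2 chains ×
1000 retained draws across 20-replicate recovery studies; exactness
checks use 10-year models where the dense joint-Gaussian oracle is
tractable, and the smoother-unbiasedness check uses 100 replicates so its
Monte-Carlo standard error is well inside the half-day tolerance. These
sizes were chosen as the smallest at which the Monte-Carlo error of each
check is comfortably below the property being asserted.

## Known limitations

* Interval *coverage* of the latent true date, pooled over a century in
  which half the years have no records, saturates near 1: backward
  extrapolation produces honest month-wide intervals that essentially
  always contain a slowly drifting truth. Calibration statements are
  therefore most meaningful over observed years.
* The walk SDs and the observation SD are only weakly separated by one
  observation per year; their posteriors lean on the prior, and the
  posterior for $\sigma_\omega$ in particular tends to sit above a small
  generating value. States, true dates and trends are robust to this.
* Phenophases are fitted independently; the model does not enforce
  FFL ≤ FFB ≤ LFB ≤ LFL within a year.
* The trend p-values treat posterior medians as data, as is conventional,
  and ignore their estimation uncertainty.
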