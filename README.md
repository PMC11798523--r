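# hanami

Bayesian estimation of the latent ("true") dates of cherry flowering
phenophases — first flowering (FFL), first full bloom (FFB), last full
bloom (LFB), last flowering (LFL) — across a century, from coarse
air-temperature predictors and sparse, noisy observation records. It is
aimed at phenologists and biostatisticians who have long daily
temperature series from a nearby weather station but flowering records
that only begin in recent decades, are scattered across sources of
varying reliability, and carry observation error.

## The model

For each phenophase and year *t*, the true date (day of year) is a
regression with *time-varying* coefficients,

```
alpha_t = mu_t + beta_t * ex1_t + gamma_t * ex2_t        (FFL, FFB)
alpha_t = mu_t + beta_t * ex3_t                          (LFB, LFL)
```

where `ex1` is the mean daily minimum temperature from 1 December to
28/29 February (winter chilling releasing bud endodormancy), `ex2` the
mean March daily temperature, and `ex3` the mean daily temperature over
1–10 April (heat forcing). Intercept and coefficients follow Gaussian
random walks,

```
mu_t = mu_{t-1} + omega_t,   omega_t ~ N(0, sigma_omega^2)   (etc.)
```

and an observed date, where one exists, is the true date plus white
noise, `y_t = alpha_t + phi_t`, `phi_t ~ N(0, sigma_phi^2)`. Years
without records are kept as latent states, so the model covers
record-free decades with honestly widening credible intervals. Inference
is by a forward-filter backward-sampling Gibbs sampler (slice updates for
the SDs); with fixed variances an exact Kalman smoother is available and
is used as an internal oracle.

## Worked example

Everything below runs on synthetic records generated at the study's
scale: 101 years of predictors (1924–2024), website-style observations
from 1989 only.

```r
library(hanami)

cfg  <- default_study_config("FFL")
sim  <- simulate_dataset(cfg, seed = 42)
spec <- build_model("FFL", sim$predictors, sim$observations)
fit  <- sample_posterior(spec, chains = 4, iterations = 12000,
                         burnin = 4000, thin = 2, seed = 7)
glance(fit)
#> # A tibble: 1 x 7
#>   phenophase n_years n_observed chains retained max_rhat min_ess
#>   <chr>        <int>      <int>  <dbl>    <dbl>    <dbl>   <dbl>
#> 1 FFL            101         36      4     4000     1.11    79.6

summ <- summarize_posterior(fit)
dplyr::filter(summ$coefficients, flavour == "pooled")
#> # A tibble: 3 x 4
#>   quantity flavour median    sd
#>   <chr>    <chr>    <dbl> <dbl>
#> 1 mu       pooled  132.   5.22
#> 2 beta     pooled   -4.40 1.78
#> 3 gamma    pooled   -4.55 0.601
```

Both temperature coefficients come out negative — a warmer winter or
March advances flowering by roughly 4 days per °C in this simulated
record. The estimated true dates carry a per-year 95% credible interval
that is a few days wide where observations exist and widens to weeks in
the record-free past:

```r
dplyr::filter(summ$states, quantity == "alpha",
              year %in% c(1924, 1950, 1989, 2024))
#> # A tibble: 4 x 5
#>    year quantity median  lo95  hi95
#>   <int> <chr>     <dbl> <dbl> <dbl>
#> 1  1924 alpha     101.   81.5 118.
#> 2  1950 alpha     114.   99.7 127.
#> 3  1989 alpha      94.9  92.6  97.2
#> 4  2024 alpha      80.0  77.6  82.5

fit_trend(summ)
#> # A tibble: 1 x 5
#>   slope_days_per_decade advance_days_per_decade r_squared  p_value n_years
#>                   <dbl>                   <dbl>     <dbl>    <dbl>   <int>
#> 1                 -2.43                    2.43     0.650 2.63e-24     101

coverage_fraction(sim$observations, summ)
#> [1] 0.9444444
```

The median true date advances by about 2.4 days/decade in this
simulation, and 94% of the observed dates lie inside their year's 95%
credible band. `autoplot(summ)` draws the ribbon-and-points figure;
`plot_coefficient_paths(summ)` shows the drifting coefficients.
Temperature and observation CSVs are read with `read_temperature_csv()` /
`read_observations_csv()`, per-year predictors computed with
`compute_predictors()`, and results serialized with
`write_state_summary_csv()` / `write_draws_csv()`.

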