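# Fixture builders; everything is generated in code at test time.

# Daily temperature tibble covering the given date range, with a simple
# seasonal shape unless constant values are requested.
make_temps <- function(from, to, tmin = NULL, tmean = NULL) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  doy <- as.integer(format(dates, "%j"))
  seasonal <- 15 + 11 * cos(2 * pi * (doy - 210) / 365.25)
  tibble::tibble(
    date = dates,
    tmin_c = if (is.null(tmin)) seasonal - 5 else rep_len(tmin, length(dates)),
    tmean_c = if (is.null(tmean)) seasonal else rep_len(tmean, length(dates))
  )
}

write_temp_fixture <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "temps.csv")
  readr::write_csv(df, path, na = "")
  path
}

# A small model spec over `n` years with hand-set predictors/observations.
make_toy_spec <- function(n = 5, phenophase = "FFL", y_obs = NULL,
                          years = seq(2000, length.out = n),
                          prior = hanami::prior_config()) {
  set.seed(99)
  predictors <- tibble::tibble(
    year = years,
    ex1 = round(stats::rnorm(n, 1.2, 0.8), 2),
    ex2 = round(stats::rnorm(n, 8, 1), 2),
    ex3 = round(stats::rnorm(n, 13, 1.3), 2)
  )
  if (is.null(y_obs)) {
    y_obs <- stats::setNames(round(stats::rnorm(n, 95, 4)), years)
  }
  obs <- tibble::tibble(
    year = as.integer(names(y_obs)), phenophase = phenophase,
    doy = as.integer(y_obs), source = "website"
  )
  hanami::build_model(phenophase, predictors, obs, prior = prior)
}

fixed_toy_variances <- function(spec) {
  p <- length(spec$state_names)
  c(sigma_omega = 0.8, sigma_tau = 0.1,
    if (p == 3) c(sigma_upsilon = 0.15), sigma_phi = 2)
}
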