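test_that("degenerate walks and zero observation noise behave exactly", {
  cfg <- default_study_config("FFL")
  frozen <- sim_config(
    phenophase = "FFL", years = cfg$years,
    initial_states = cfg$initial_states,
    sigmas = c(sigma_omega = 0, sigma_tau = 0, sigma_upsilon = 0,
               sigma_phi = 0),
    predictor_model = cfg$predictor_model, obs_start = cfg$obs_start
  )
  sim <- simulate_dataset(frozen, seed = 14)
  # all process SDs zero: coefficient paths are flat
  expect_equal(unique(sim$truth$mu), cfg$initial_states[["mu"]])
  expect_equal(unique(sim$truth$beta), cfg$initial_states[["beta"]])
  expect_equal(unique(sim$truth$gamma), cfg$initial_states[["gamma"]])
  # no observation noise: observed DOY is the rounded true date
  idx <- match(sim$observations$year, sim$truth$year)
  expect_equal(sim$observations$doy, as.integer(round(sim$truth$alpha[idx])))
})

test_that("random-walk increments reproduce the generating SD", {
  cfg <- default_study_config("LFB")
  long <- sim_config(
    phenophase = "LFB", years = 1:10001,
    initial_states = c(mu = 130, beta = -2.2),
    sigmas = c(sigma_omega = 1, sigma_tau = 0, sigma_phi = 1),
    predictor_model = cfg$predictor_model,
    obs_start = 20000   # no observations needed here
  )
  sim <- simulate_dataset(long, seed = 15)
  inc <- diff(sim$truth$mu)
  expect_gt(sd(inc), 0.97)   # Monte-Carlo band around the generating SD of 1
  expect_lt(sd(inc), 1.03)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- default_study_config("FFB")
  a <- simulate_dataset(cfg, seed = 77)
  b <- simulate_dataset(cfg, seed = 77)
  expect_identical(a$predictors, b$predictors)
  expect_identical(a$truth, b$truth)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$truth, simulate_dataset(cfg, seed = 78)$truth))
})

test_that("shipped configuration matches the recorded series' magnitudes", {
  doy <- unlist(lapply(1:28, function(s) {
    simulate_dataset(default_study_config("FFL"), seed = s)$observations$doy
  }))
  expect_gt(length(doy), 1000)
  expect_gt(mean(doy), 90)        # long-run observed mean near DOY 92
  expect_lt(mean(doy), 94)
  expect_gt(sd(doy), 4)           # interannual spread near 6 days
  expect_lt(sd(doy), 8)
})

test_that("last-flowering observations only start in 2002", {
  sim <- simulate_dataset(default_study_config("LFL"), seed = 16)
  expect_equal(min(sim$observations$year), 2002)
  early <- simulate_dataset(default_study_config("FFL"), seed = 16)
  expect_equal(min(early$observations$year), 1989)
})

test_that("a warming trend advances the simulated true dates", {
  cfg <- default_study_config("FFL")
  frozen <- sim_config(
    phenophase = "FFL", years = cfg$years,
    initial_states = cfg$initial_states,
    sigmas = c(sigma_omega = 0, sigma_tau = 0, sigma_upsilon = 0,
               sigma_phi = 0),
    predictor_model = cfg$predictor_model, obs_start = cfg$obs_start
  )
  sim <- simulate_dataset(frozen, seed = 17)
  tr <- fit_trend(sim$truth, value_col = "alpha")
  expect_lt(tr$slope_days_per_decade, 0)   # negative coefficients x warming
  expect_gt(tr$advance_days_per_decade, 0)
})

test_that("historical observations append under their own source label", {
  sim <- simulate_dataset(default_study_config("FFB"), seed = 18)
  n0 <- nrow(sim$observations)
  aug <- add_historical_observations(sim, 1928:1937, source = "literature",
                                     seed = 2)
  expect_equal(nrow(aug$observations), n0 + 10)
  lit <- aug$observations[aug$observations$source == "literature", ]
  expect_equal(lit$year, 1928:1937)
  idx <- match(lit$year, aug$truth$year)
  expect_lt(max(abs(lit$doy - aug$truth$alpha[idx])), 10)  # noisy copies of truth
  expect_error(add_historical_observations(sim, 1800:1810), "inside")
})

test_that("daily-weather mode exercises the temperature-to-predictor path", {
  cfg <- default_study_config("FFL")
  daily <- sim_config(
    phenophase = "FFL", years = 1990:2000,
    initial_states = cfg$initial_states, sigmas = cfg$sigmas,
    predictor_model = cfg$predictor_model, obs_start = 1990,
    predictor_mode = "daily"
  )
  sim <- simulate_dataset(daily, seed = 19)
  expect_false(anyNA(sim$predictors$ex1))
  # window means land in plausible bands around the annual-mode climatology
  expect_gt(mean(sim$predictors$ex1), -2)
  expect_lt(mean(sim$predictors$ex1), 4)
  expect_gt(mean(sim$predictors$ex2), 6)
  expect_lt(mean(sim$predictors$ex2), 10)
  expect_gt(mean(sim$predictors$ex3), 9)
  expect_lt(mean(sim$predictors$ex3), 14)
  expect_equal(nrow(sim$observations), 11)
})

test_that("exact smoothing with the generating variances is unbiased for truth", {
  # per-replicate mean error is dominated by the (unbiased) backward
  # extrapolation into unobserved years, with SD ~2 days; 100 replicates
  # bring the Monte-Carlo SE of the mean well inside the half-day band
  errs <- vapply(1:100, function(s) {
    cfg <- default_study_config("FFL")
    sim <- simulate_dataset(cfg, seed = 400 + s)
    spec <- build_model("FFL", sim$predictors, sim$observations)
    sm <- kalman_smoother(spec, cfg$sigmas)
    alpha <- sm$mean[sm$quantity == "alpha"]
    mean(alpha - sim$truth$alpha)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
})
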