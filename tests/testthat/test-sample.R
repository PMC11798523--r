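test_that("identical seed, spec and settings reproduce the draws exactly", {
  spec <- make_toy_spec(n = 6)
  fit1 <- suppressWarnings(sample_posterior(spec, chains = 2, iterations = 200,
                                            burnin = 50, thin = 2, seed = 123))
  fit2 <- suppressWarnings(sample_posterior(spec, chains = 2, iterations = 200,
                                            burnin = 50, thin = 2, seed = 123))
  expect_identical(fit1$chains[[1]]$alpha, fit2$chains[[1]]$alpha)
  expect_identical(fit1$chains[[2]]$sigma, fit2$chains[[2]]$sigma)
  fit3 <- suppressWarnings(sample_posterior(spec, chains = 2, iterations = 200,
                                            burnin = 50, thin = 2, seed = 124))
  expect_false(identical(fit1$chains[[1]]$alpha, fit3$chains[[1]]$alpha))
})

test_that("with negligible noise the true date sticks to the observations", {
  spec <- make_toy_spec(n = 6)
  tiny <- c(sigma_omega = 1e-3, sigma_tau = 1e-3, sigma_upsilon = 1e-3,
            sigma_phi = 1e-3)
  fit <- sample_posterior(spec, chains = 2, iterations = 600, burnin = 100,
                          thin = 1, seed = 4, fix_variances = tiny)
  alpha <- summarize_posterior(fit)$states
  alpha <- alpha[alpha$quantity == "alpha", ]
  observed <- !is.na(spec$y)
  expect_equal(alpha$median[observed], spec$y[observed], tolerance = 1e-2)
})

test_that("retained length and shapes follow the thinning arithmetic", {
  spec <- make_toy_spec(n = 4)
  fit <- suppressWarnings(sample_posterior(spec, chains = 3, iterations = 110,
                                           burnin = 30, thin = 4, seed = 1))
  expect_equal(fit$settings$retained, 20)
  expect_equal(dim(fit$chains[[1]]$alpha), c(20, 4))
  expect_equal(dim(fit$chains[[2]]$states), c(20, 4, 3))
  expect_error(sample_posterior(spec, iterations = 100, burnin = 100), "burnin")
  expect_error(sample_posterior(spec, chains = 0), "positive")
})

test_that("credible intervals use type-7 quantiles and stay ordered", {
  spec <- make_toy_spec(n = 1)
  fake_chain <- list(
    alpha = matrix(1:100, dimnames = list(NULL, "2000")),
    states = array(rep(1:100, 3), c(100, 1, 3),
                   dimnames = list(NULL, "2000", c("mu", "beta", "gamma"))),
    sigma = matrix(1, 100, 4,
                   dimnames = list(NULL, c("sigma_omega", "sigma_tau",
                                           "sigma_upsilon", "sigma_phi")))
  )
  fake <- structure(list(spec = spec, chains = list(fake_chain),
                         settings = list(retained = 100)),
                    class = "pheno_fit")
  s <- summarize_posterior(fake)
  alpha <- s$states[s$states$quantity == "alpha", ]
  expect_equal(alpha$median, 50.5)
  expect_equal(alpha$lo95, 3.475)     # linear-interpolation quantile rule
  expect_equal(alpha$hi95, 97.525)

  # constant draws collapse the interval
  fake$chains[[1]]$alpha[] <- 7
  s2 <- summarize_posterior(fake)
  a2 <- s2$states[s2$states$quantity == "alpha", ]
  expect_equal(c(a2$median, a2$lo95, a2$hi95), c(7, 7, 7))

  # ordering invariant on a real stochastic fit
  fit <- suppressWarnings(sample_posterior(make_toy_spec(n = 5), chains = 2,
                                           iterations = 300, burnin = 100,
                                           thin = 2, seed = 31))
  st <- summarize_posterior(fit)$states
  expect_true(all(st$lo95 <= st$median & st$median <= st$hi95))
})

test_that("dropping the March term reduces the early-phase model to the late form", {
  set.seed(5)
  years <- 2000:2011
  predictors <- tibble::tibble(year = years, ex1 = rnorm(12, 1.2, 0.8),
                               ex2 = 0, ex3 = rnorm(12, 13, 1))
  obs <- tibble::tibble(year = years[c(2, 5, 8, 11)], phenophase = "FFL",
                        doy = c(95L, 92L, 97L, 90L), source = "website")
  spec_ffl <- build_model("FFL", predictors, obs)
  obs_lfb <- dplyr::mutate(obs, phenophase = "LFB")
  # same predictor enters the one-coefficient form
  spec_lfb <- build_model("LFB", dplyr::rename(predictors, ex3_drop = ex3,
                                               ex3 = ex1), obs_lfb)
  v2 <- c(sigma_omega = 0.5, sigma_tau = 0.05, sigma_phi = 2)
  v3 <- c(v2[c("sigma_omega", "sigma_tau")], sigma_upsilon = 1e-4,
          sigma_phi = 2)
  fit3 <- sample_posterior(spec_ffl, chains = 2, iterations = 2200,
                           burnin = 200, thin = 1, seed = 6,
                           fix_variances = v3)
  fit2 <- sample_posterior(spec_lfb, chains = 2, iterations = 2200,
                           burnin = 200, thin = 1, seed = 7,
                           fix_variances = v2)
  a3 <- tidy(fit3)
  a2 <- tidy(fit2)
  m3 <- a3$median[a3$quantity == "alpha"]
  m2 <- a2$median[a2$quantity == "alpha"]
  expect_equal(m3, m2, tolerance = 0.05)   # Monte-Carlo agreement
})

test_that("tidy and glance expose the summary and fit overview", {
  spec <- make_toy_spec(n = 5)
  fit <- suppressWarnings(sample_posterior(spec, chains = 2, iterations = 300,
                                           burnin = 100, thin = 2, seed = 9))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("year", "quantity", "median", "lo95", "hi95"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_years, 5)
  expect_equal(gl$chains, 2)
  expect_true(is.finite(gl$max_rhat))
})

test_that("split-R-hat flags disagreeing chains and passes agreeing ones", {
  set.seed(42)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.02)
  bad <- good
  bad[, 4] <- bad[, 4] + 5
  expect_gt(split_rhat(bad), 1.5)
  expect_true(ess_basic(good) > 2000)   # near-independent draws
})
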