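#' Exact Kalman filter/smoother for a phenophase model at fixed variances
#'
#' With the random-walk SDs and observation SD held fixed, the phenophase
#' model is linear-Gaussian, so the posterior of the latent states is
#' available in closed form. This routine runs the forward Kalman filter
#' and the Rauch-Tung-Striebel smoother and returns the exact per-year
#' Gaussian marginals of the intercept, coefficients and derived true date
#' `alpha_t`. Years without an observation are handled as prediction-only
#' steps. It serves both as a fast fixed-variance estimator and as the
#' exact-inference reference for the MCMC sampler.
#'
#' @param spec A `pheno_model` from [build_model()].
#' @param variances Named list/vector of SDs: `sigma_omega` (intercept
#'   walk), `sigma_tau` (beta walk), `sigma_upsilon` (gamma walk; only for
#'   two-predictor models), `sigma_phi` (observation error), all in days.
#' @param initial_sd Diffuse SD for the initial state; defaults to the
#'   model's prior setting.
#' @return Tibble with columns `year, quantity, mean, sd`, quantity in
#'   `alpha, mu, beta[, gamma]`.
#' @export
kalman_smoother <- function(spec, variances, initial_sd = NULL) {
  stopifnot(inherits(spec, "pheno_model"))
  v <- check_variances(spec, variances)
  p <- length(spec$state_names)
  n <- length(spec$years)
  initial_sd <- initial_sd %||% spec$prior$initial_sd
  W <- diag(v[seq_len(p)]^2, p)
  sig2_phi <- v[["sigma_phi"]]^2

  m <- matrix(0, p, n)            # filtered means
  C <- array(0, c(p, p, n))       # filtered covariances
  a <- matrix(0, p, n)            # one-step predicted means
  R <- array(0, c(p, p, n))       # one-step predicted covariances
  for (t in seq_len(n)) {
    if (t == 1) {
      a[, 1] <- 0
      R[, , 1] <- diag(initial_sd^2, p)
    } else {
      a[, t] <- m[, t - 1]
      R[, , t] <- C[, , t - 1] + W
    }
    Ft <- spec$X[t, ]
    if (is.na(spec$y[t])) {
      m[, t] <- a[, t]
      C[, , t] <- R[, , t]
    } else {
      Rt <- R[, , t]
      Q <- drop(crossprod(Ft, Rt %*% Ft)) + sig2_phi
      if (!is.finite(Q) || Q <= 0) {
        abort(paste0("non-positive innovation variance at year ", spec$years[t]))
      }
      K <- (Rt %*% Ft) / Q
      m[, t] <- a[, t] + K * drop(spec$y[t] - crossprod(Ft, a[, t]))
      Ct <- Rt - K %*% crossprod(Ft, Rt)
      C[, , t] <- (Ct + t(Ct)) / 2
    }
  }

  s <- matrix(0, p, n)            # smoothed means
  S <- array(0, c(p, p, n))       # smoothed covariances
  s[, n] <- m[, n]
  S[, , n] <- C[, , n]
  for (t in rev(seq_len(n - 1))) {
    Rn <- R[, , t + 1]
    J <- C[, , t] %*% solve(Rn)
    s[, t] <- m[, t] + J %*% (s[, t + 1] - a[, t + 1])
    St <- C[, , t] + J %*% (S[, , t + 1] - Rn) %*% t(J)
    St <- (St + t(St)) / 2
    if (any(diag(St) < -1e-8)) {
      abort(paste0("propagated covariance lost positive-definiteness at year ",
                   spec$years[t]))
    }
    S[, , t] <- St
  }

  alpha_mean <- vapply(seq_len(n), function(t) drop(crossprod(spec$X[t, ], s[, t])),
                       numeric(1))
  alpha_sd <- vapply(seq_len(n), function(t) {
    sqrt(max(drop(crossprod(spec$X[t, ], S[, , t] %*% spec$X[t, ])), 0))
  }, numeric(1))

  state_rows <- purrr::map_dfr(seq_len(p), function(j) {
    tibble::tibble(year = spec$years, quantity = spec$state_names[j],
                   mean = s[j, ], sd = sqrt(pmax(S[j, j, ], 0)))
  })
  dplyr::bind_rows(
    tibble::tibble(year = spec$years, quantity = "alpha",
                   mean = alpha_mean, sd = alpha_sd),
    state_rows
  ) |>
    dplyr::arrange(factor(.data$quantity, levels = c("alpha", spec$state_names)),
                   .data$year)
}
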