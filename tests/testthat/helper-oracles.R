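# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force predictor oracle: enumerates the window's dates month by month
# and averages the matching daily values.
oracle_window_dates <- function(year, window) {
  md <- function(y, m, days) as.Date(sprintf("%d-%02d-%02d", y, m, days))
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  switch(window,
    winter = c(md(year - 1, 12, 1:31), md(year, 1, 1:31),
               md(year, 2, seq_len(if (leap) 29 else 28))),
    march = md(year, 3, 1:31),
    april10 = md(year, 4, 1:10)
  )
}

oracle_window_mean <- function(temps, year, window, column) {
  dates <- oracle_window_dates(year, window)
  vals <- temps[[column]][match(dates, temps$date)]
  mean(vals, na.rm = TRUE)
}

# Dense joint-Gaussian conditioning oracle for the fixed-variance model:
# builds the full prior covariance of every latent state across all years
# (independent random walks from a diffuse start), conditions on the
# observed dates, and reads off the exact posterior mean/SD of each state
# and of the derived true date alpha_t.
oracle_joint_gaussian <- function(spec, variances, initial_sd = NULL) {
  initial_sd <- if (is.null(initial_sd)) spec$prior$initial_sd else initial_sd
  p <- ncol(spec$X)
  n <- length(spec$years)
  proc_sd <- unname(unlist(variances)[c("sigma_omega", "sigma_tau",
                                        if (p == 3) "sigma_upsilon")])
  sigma_phi <- unlist(variances)[["sigma_phi"]]
  N <- n * p
  idx <- function(t, j) (j - 1) * n + t
  Sigma <- matrix(0, N, N)
  for (j in seq_len(p)) {
    for (t1 in seq_len(n)) {
      for (t2 in seq_len(n)) {
        Sigma[idx(t1, j), idx(t2, j)] <-
          initial_sd^2 + (min(t1, t2) - 1) * proc_sd[j]^2
      }
    }
  }
  obs_t <- which(!is.na(spec$y))
  H <- matrix(0, length(obs_t), N)
  for (i in seq_along(obs_t)) {
    for (j in seq_len(p)) H[i, idx(obs_t[i], j)] <- spec$X[obs_t[i], j]
  }
  Syy <- H %*% Sigma %*% t(H) + diag(sigma_phi^2, length(obs_t))
  Sxy <- Sigma %*% t(H)
  gain <- Sxy %*% solve(Syy)
  post_mean <- as.vector(gain %*% spec$y[obs_t])
  post_cov <- Sigma - gain %*% t(Sxy)

  state_names <- spec$state_names
  out <- list()
  for (j in seq_len(p)) {
    rows <- idx(seq_len(n), j)
    out[[state_names[j]]] <- data.frame(
      year = spec$years, mean = post_mean[rows],
      sd = sqrt(pmax(diag(post_cov)[rows], 0))
    )
  }
  alpha_mean <- numeric(n)
  alpha_sd <- numeric(n)
  for (t in seq_len(n)) {
    w <- numeric(N)
    for (j in seq_len(p)) w[idx(t, j)] <- spec$X[t, j]
    alpha_mean[t] <- sum(w * post_mean)
    alpha_sd[t] <- sqrt(max(drop(t(w) %*% post_cov %*% w), 0))
  }
  out$alpha <- data.frame(year = spec$years, mean = alpha_mean, sd = alpha_sd)
  out
}

# Closed-form OLS via the normal equations (trend oracle).
oracle_ols <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum(yc^2)
  n <- length(x)
  se <- sqrt(ss_res / (n - 2) / sum(xc^2))
  tval <- slope / se
  list(slope = slope, r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
}
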