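#' Draw from the posterior of a phenophase state-space model
#'
#' Gibbs sampler alternating (i) an exact forward-filter backward-sampling
#' draw of the whole latent state path given the variance parameters and
#' (ii) slice-sampling updates of the random-walk and observation SDs given
#' the states. Multiple chains are run from dispersed variance starting
#' values; split-R-hat and effective sample size are computed for the
#' variance parameters and the per-year true dates and attached to the
#' result (a warning is raised, never silenced, when R-hat exceeds 1.05).
#'
#' @param spec A `pheno_model` from [build_model()].
#' @param chains Number of chains (default 4).
#' @param iterations Sampler iterations per chain, including burn-in
#'   (default 5000).
#' @param burnin Burn-in iterations discarded per chain (default 1000).
#' @param thin Thinning interval (default 2); the retained length per chain
#'   is `(iterations - burnin) / thin`.
#' @param seed Integer seed; the same seed, spec and settings reproduce the
#'   draws exactly.
#' @param fix_variances Optional named SD vector (`sigma_omega`,
#'   `sigma_tau`, `sigma_upsilon` where applicable, `sigma_phi`). When
#'   supplied the
#'   variance parameters are held fixed and only the states are sampled —
#'   the regime in which the Kalman smoother gives the exact answer.
#' @return An object of class `pheno_fit`.
#' @export
sample_posterior <- function(spec, chains = 4, iterations = 5000,
                             burnin = 1000, thin = 2, seed = 1,
                             fix_variances = NULL) {
  stopifnot(inherits(spec, "pheno_model"))
  if (chains < 1 || iterations < 1 || burnin < 0 || thin < 1) {
    abort("MCMC settings must be positive (burnin may be zero)")
  }
  if (burnin >= iterations) abort("burnin must be smaller than iterations")
  p <- length(spec$state_names)
  fixed <- !is.null(fix_variances)
  if (fixed) {
    sigma_fixed <- check_variances(spec, fix_variances)
  }
  prior_type <- if (spec$prior$sigma_prior == "halfnormal") 0L else 1L
  observed <- as.integer(!is.na(spec$y))
  y <- ifelse(is.na(spec$y), 0, spec$y)

  set.seed(as.integer(seed))
  chain_draws <- purrr::map(seq_len(chains), function(ch) {
    sigma_init <- if (fixed) {
      unname(sigma_fixed)
    } else {
      # dispersed but ordered starting values across chains
      rep(c(0.5, 1, 2, 5)[((ch - 1) %% 4) + 1], p + 1)
    }
    res <- gibbs_dlm_cpp(y, observed, spec$X, spec$prior$initial_sd,
                         sigma_init, fixed, spec$prior$sigma_scale,
                         prior_type, as.integer(iterations),
                         as.integer(burnin), as.integer(thin))
    dimnames(res$states) <- list(NULL, spec$years, spec$state_names)
    colnames(res$sigma) <- sigma_parameter_names(spec)
    colnames(res$alpha) <- spec$years
    res
  })

  fit <- structure(
    list(spec = spec, chains = chain_draws,
         settings = list(chains = chains, iterations = iterations,
                         burnin = burnin, thin = thin, seed = seed,
                         retained = (iterations - burnin) %/% thin,
                         fixed_variances = fixed)),
    class = "pheno_fit"
  )
  fit$diagnostics <- convergence_diagnostics(fit)
  bad <- fit$diagnostics$rhat > 1.05
  if (chains > 1 && any(bad, na.rm = TRUE)) {
    warn(paste0("split-R-hat above 1.05 for: ",
                paste(utils::head(fit$diagnostics$parameter[which(bad)], 5),
                      collapse = ", "),
                " (max ", round(max(fit$diagnostics$rhat, na.rm = TRUE), 3), ")"))
  }
  fit
}

sigma_parameter_names <- function(spec) {
  p <- length(spec$state_names)
  c("sigma_omega", "sigma_tau", if (p == 3) "sigma_upsilon", "sigma_phi")
}

# draws of one scalar parameter as a (retained x chains) matrix
parameter_matrix <- function(fit, parameter) {
  vapply(fit$chains, function(ch) {
    if (parameter %in% colnames(ch$sigma)) {
      ch$sigma[, parameter]
    } else if (grepl("^alpha\\[", parameter)) {
      yr <- sub("^alpha\\[(\\d+)\\]$", "\\1", parameter)
      ch$alpha[, yr]
    } else {
      m <- regmatches(parameter, regexec("^(\\w+)\\[(\\d+)\\]$", parameter))[[1]]
      ch$states[, m[3], m[2]]
    }
  }, numeric(fit$settings$retained))
}

# all retained draws pooled across chains, long format
draws_long <- function(fit) {
  spec <- fit$spec
  purrr::imap_dfr(fit$chains, function(ch, i) {
    sig <- tibble::as_tibble(ch$sigma) |>
      dplyr::mutate(chain = i, iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(-c("chain", "iteration"),
                          names_to = "parameter", values_to = "value")
    al <- tibble::as_tibble(ch$alpha, .name_repair = ~ paste0("alpha[", .x, "]")) |>
      dplyr::mutate(chain = i, iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(-c("chain", "iteration"),
                          names_to = "parameter", values_to = "value")
    st <- purrr::map_dfr(spec$state_names, function(q) {
      tibble::as_tibble(ch$states[, , q],
                        .name_repair = ~ paste0(q, "[", .x, "]")) |>
        dplyr::mutate(chain = i, iteration = dplyr::row_number()) |>
        tidyr::pivot_longer(-c("chain", "iteration"),
                            names_to = "parameter", values_to = "value")
    })
    dplyr::bind_rows(sig, al, st)
  }) |>
    dplyr::select("chain", "iteration", "parameter", "value")
}

#' Summarize a posterior fit per year
#'
#' Per-year posterior medians and central 95% credible intervals (2.5% and
#' 97.5% linear-interpolation quantiles, R type 7) of the true date
#' `alpha_t`, intercept `mu_t` and temperature coefficients, pooling all
#' retained draws across chains; plus pooled coefficient summaries in two
#' labelled flavours: `pooled` (median/SD across all years and draws) and
#' `time_averaged` (median/SD over draws of each draw's across-year mean).
#'
#' @param fit A `pheno_fit` (or draws retained from one).
#' @return An object of class `pheno_summary` with elements `states`
#'   (tibble `year,quantity,median,lo95,hi95`), `coefficients`, and the
#'   phenophase/observation metadata needed downstream.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  if (length(fit$chains) == 0 || fit$settings$retained == 0) {
    abort("no retained draws to summarize")
  }
  spec <- fit$spec
  pool_states <- function(q) {
    do.call(rbind, purrr::map(fit$chains, function(ch) {
      if (q == "alpha") ch$alpha else ch$states[, , q]
    }))
  }
  summarize_mat <- function(mat, q) {
    tibble::tibble(
      year = spec$years,
      quantity = q,
      median = unname(apply(mat, 2, median)),
      lo95 = unname(apply(mat, 2, quantile, probs = 0.025, type = 7)),
      hi95 = unname(apply(mat, 2, quantile, probs = 0.975, type = 7))
    )
  }
  quantities <- c("alpha", spec$state_names)
  states <- purrr::map_dfr(quantities, ~ summarize_mat(pool_states(.x), .x))

  coefficients <- purrr::map_dfr(spec$state_names, function(q) {
    mat <- pool_states(q)              # draws x years
    dplyr::bind_rows(
      tibble::tibble(quantity = q, flavour = "pooled",
                     median = median(mat), sd = sd(mat)),
      tibble::tibble(quantity = q, flavour = "time_averaged",
                     median = median(rowMeans(mat)), sd = sd(rowMeans(mat)))
    )
  })
  sigmas <- purrr::map_dfr(sigma_parameter_names(spec), function(s) {
    v <- unlist(purrr::map(fit$chains, ~ .x$sigma[, s]))
    tibble::tibble(parameter = s, median = median(v),
                   lo95 = quantile(v, 0.025, names = FALSE),
                   hi95 = quantile(v, 0.975, names = FALSE))
  })

  structure(
    list(states = states, coefficients = coefficients, variances = sigmas,
         phenophase = spec$phenophase, observations = spec$observations,
         years = spec$years),
    class = "pheno_summary"
  )
}

#' @export
print.pheno_fit <- function(x, ...) {
  s <- x$settings
  cat("<pheno_fit> ", x$spec$phenophase, ": ", length(x$spec$years),
      " years, ", sum(!is.na(x$spec$y)), " observed\n",
      s$chains, " chain(s) x ", s$retained, " retained draws",
      if (s$fixed_variances) " (variances fixed)", "\n", sep = "")
  if (!is.null(x$diagnostics)) {
    cat("max split-R-hat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
        ", min ESS ", round(min(x$diagnostics$ess, na.rm = TRUE)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.pheno_summary <- function(x, ...) {
  cat("<pheno_summary> ", x$phenophase, ": ", length(x$years), " years\n", sep = "")
  print(x$states)
  invisible(x)
}

#' Tidy a posterior fit into the per-year state summary
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return The `states` tibble of [summarize_posterior()].
#' @export
tidy.pheno_fit <- function(x, ...) {
  summarize_posterior(x)$states
}

#' One-row overview of a posterior fit
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return A one-row tibble: phenophase, sizes, MCMC settings, worst
#'   split-R-hat and smallest effective sample size.
#' @export
glance.pheno_fit <- function(x, ...) {
  tibble::tibble(
    phenophase = x$spec$phenophase,
    n_years = length(x$spec$years),
    n_observed = sum(!is.na(x$spec$y)),
    chains = x$settings$chains,
    retained = x$settings$retained,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}
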