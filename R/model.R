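#' Prior configuration for the state-space phenology model
#'
#' The initial latent states (intercept and temperature coefficients) get a
#' diffuse Normal(0, `initial_sd`^2) prior approximating a non-informative
#' uniform; the random-walk and observation SDs get either a half-normal
#' prior of scale `sigma_scale` days (default, weakly informative — it
#' stabilises century-long unobserved stretches) or an improper flat prior
#' on the positive half-line.
#'
#' @param initial_sd Diffuse SD for the initial states, in days and
#'   days/degree C (default 100, i.e. variance 1e4).
#' @param sigma_prior `"halfnormal"` (default) or `"flat"`.
#' @param sigma_scale Half-normal scale for each SD parameter, days
#'   (default 10). Ignored for the flat prior.
#' @return An object of class `pheno_prior`.
#' @export
prior_config <- function(initial_sd = 100,
                         sigma_prior = c("halfnormal", "flat"),
                         sigma_scale = 10) {
  sigma_prior <- match.arg(sigma_prior)
  if (initial_sd <= 0 || sigma_scale <= 0) {
    abort("prior scales must be strictly positive")
  }
  structure(
    list(initial_sd = initial_sd, sigma_prior = sigma_prior,
         sigma_scale = sigma_scale),
    class = "pheno_prior"
  )
}

#' Build a phenophase state-space model specification
#'
#' Assembles one of the two model forms over the contiguous run of years
#' with complete predictors: for FFL/FFB the true date is
#' `alpha_t = mu_t + beta_t * ex1_t + gamma_t * ex2_t`; for LFB/LFL it is
#' `alpha_t = mu_t + beta_t * ex3_t`. Intercept and coefficients follow
#' independent Gaussian random walks, and the observed date is the true
#' date plus Gaussian noise. Years without an observation are retained as
#' unobserved states (the state equations propagate; the observation
#' equation is skipped), which is what lets the model cover record-free
#' decades.
#'
#' @param phenophase One of `"FFL"`, `"FFB"`, `"LFB"`, `"LFL"`.
#' @param predictors Predictor tibble from [compute_predictors()] (or the
#'   synthetic generator): columns `year` plus `ex1`/`ex2` or `ex3`.
#' @param observations Observation tibble (columns
#'   `year,phenophase,doy,source`); conflicting sources are resolved by
#'   `precedence`.
#' @param prior A [prior_config()].
#' @param precedence Source precedence, highest first.
#' @param observation_mask Optional integer vector of years whose
#'   observations are dropped before fitting (e.g. a low-vigour era of the
#'   tree); by default no years are masked.
#' @return An object of class `pheno_model`: the year range, design matrix,
#'   per-year observation vector (`NA` = unobserved) and prior.
#' @export
build_model <- function(phenophase, predictors, observations,
                        prior = prior_config(),
                        precedence = default_source_precedence(),
                        observation_mask = NULL) {
  phenophase <- match.arg(toupper(phenophase), PHENOPHASES)
  two_pred <- phenophase %in% two_predictor_phenophases()
  pred_cols <- if (two_pred) c("ex1", "ex2") else "ex3"
  missing_cols <- setdiff(c("year", pred_cols), names(predictors))
  if (length(missing_cols)) {
    abort(paste0("predictor table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  predictors <- dplyr::arrange(tibble::as_tibble(predictors), .data$year)
  complete <- stats::complete.cases(predictors[pred_cols])
  if (!any(complete)) abort("all predictors missing; nothing to model")
  years_avail <- predictors$year[complete]
  run <- longest_contiguous_run(years_avail)
  dropped <- setdiff(predictors$year, run)
  if (length(dropped)) {
    inform(paste0("excluding ", length(dropped),
                  " year(s) outside the longest contiguous predictor run (",
                  min(run), "-", max(run), ")"))
  }
  predictors <- predictors[predictors$year %in% run, , drop = FALSE]

  obs <- resolve_observations(observations, phenophase, precedence)
  if (!is.null(observation_mask)) {
    obs <- obs[!obs$year %in% observation_mask, , drop = FALSE]
  }
  outside <- setdiff(obs$year, run)
  if (length(outside)) {
    warn(paste0("dropping observation(s) outside predictor coverage: ",
                paste(outside, collapse = ", ")))
    obs <- obs[obs$year %in% run, , drop = FALSE]
  }
  if (nrow(obs) == 0) abort("no usable observations for this phenophase")

  years <- predictors$year
  X <- cbind(intercept = 1, as.matrix(predictors[pred_cols]))
  y <- rep(NA_real_, length(years))
  y[match(obs$year, years)] <- as.numeric(obs$doy)

  structure(
    list(phenophase = phenophase, years = years, X = X, y = y,
         predictors = predictors, observations = obs, prior = prior,
         state_names = c("mu", "beta", if (two_pred) "gamma")),
    class = "pheno_model"
  )
}

longest_contiguous_run <- function(years) {
  grp <- cumsum(c(1L, diff(years) != 1L))
  best <- names(which.max(table(grp)))
  years[grp == as.integer(best)]
}

#' @export
print.pheno_model <- function(x, ...) {
  cat("<pheno_model> ", x$phenophase, ": ", min(x$years), "-", max(x$years),
      " (", length(x$years), " years, ", sum(!is.na(x$y)), " observed)\n",
      "states: ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Named SD vector (process walks then observation) checked against a model.
check_variances <- function(spec, variances) {
  p <- length(spec$state_names)
  need <- c("sigma_omega", "sigma_tau", if (p == 3) "sigma_upsilon", "sigma_phi")
  variances <- unlist(variances)
  missing_v <- setdiff(need, names(variances))
  if (length(missing_v)) {
    abort(paste0("variances must name: ", paste(need, collapse = ", ")))
  }
  v <- variances[need]
  if (any(v <= 0)) abort("all SD parameters must be strictly positive")
  v
}
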