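#' Split-R-hat of a set of chains
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half (rank-free version of the standard between/within-variance
#' diagnostic). Values near 1 indicate the chains agree; above ~1.05 the
#' sampler should be run longer.
#'
#' @param draws Numeric matrix, retained iterations in rows, chains in
#'   columns.
#' @return A single R-hat value (`NA` if the draws are constant).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size of pooled chains
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence
#' truncation, averaged over chains.
#'
#' @param draws Numeric matrix, iterations in rows, chains in columns.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  rho <- rowMeans(apply(draws, 2, function(x) {
    if (stats::var(x) == 0) return(rep(0, n))
    a <- stats::acf(x, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }))
  # sum paired lags while the pair sums stay positive
  tau <- 1
  k <- 1
  while (k + 1 < length(rho)) {
    pair <- rho[k + 1] + rho[k + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(n * ncol(draws) / tau, 1)
}

#' Convergence diagnostics for every monitored parameter
#'
#' @param fit A `pheno_fit`.
#' @return Tibble `parameter, rhat, ess` covering the variance SDs and the
#'   per-year true dates.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "pheno_fit"))
  params <- c(sigma_parameter_names(fit$spec),
              paste0("alpha[", fit$spec$years, "]"))
  purrr::map_dfr(params, function(pm) {
    mat <- parameter_matrix(fit, pm)
    tibble::tibble(parameter = pm, rhat = split_rhat(mat), ess = ess_basic(mat))
  })
}
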