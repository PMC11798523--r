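#' Linear trend of a per-year quantity, in days per decade
#'
#' Ordinary least-squares regression of a per-year series (typically the
#' posterior median of the true phenophase date) on calendar year. The
#' slope is reported times ten as days/decade; a negative slope means the
#' date is advancing, and `advance_days_per_decade` is its magnitude
#' (zero when the trend is a delay). R-squared and the two-sided p-value
#' come from the standard linear-regression t statistic.
#'
#' @param data A data frame with a year column and a value column, or a
#'   `pheno_summary` (its `alpha` medians are used).
#' @param year_col,value_col Column names (defaults `"year"`, `"median"`).
#' @return A one-row tibble: `slope_days_per_decade`,
#'   `advance_days_per_decade`, `r_squared`, `p_value`, `n_years`.
#' @export
fit_trend <- function(data, year_col = "year", value_col = "median") {
  if (inherits(data, "pheno_summary")) {
    data <- dplyr::filter(data$states, .data$quantity == "alpha")
  }
  years <- data[[year_col]]
  values <- data[[value_col]]
  keep <- !is.na(years) & !is.na(values)
  years <- years[keep]
  values <- values[keep]
  if (length(years) < 3) abort("need at least 3 (year, value) pairs")
  if (anyDuplicated(years)) abort("years must be distinct")
  if (stats::var(years) == 0) abort("zero variance in years")
  if (stats::var(values) == 0) {
    # a flat series has no trend; summary.lm would return 0/0 here
    return(tibble::tibble(slope_days_per_decade = 0,
                          advance_days_per_decade = 0, r_squared = 0,
                          p_value = 1, n_years = length(years)))
  }
  fit <- lm(values ~ years)
  sm <- summary(fit)
  slope <- coef(fit)[["years"]] * 10
  tibble::tibble(
    slope_days_per_decade = slope,
    advance_days_per_decade = max(-slope, 0),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["years", "Pr(>|t|)"],
    n_years = length(years)
  )
}

#' Fraction of observations inside the 95% credible interval
#'
#' For each observed year present in the summary, checks whether the
#' observed DOY lies within the credible interval of the estimated true
#' date; conflicts between sources are first resolved to one value per
#' year.
#'
#' @param observations Observation tibble (`year,phenophase,doy,source`).
#' @param summary A `pheno_summary` or a state-summary tibble restricted to
#'   one phenophase.
#' @param phenophase Needed only when `summary` is a plain tibble.
#' @param precedence Source precedence, highest first.
#' @return A single fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(observations, summary, phenophase = NULL,
                              precedence = default_source_precedence()) {
  if (inherits(summary, "pheno_summary")) {
    phenophase <- summary$phenophase
    states <- summary$states
  } else {
    if (is.null(phenophase)) abort("phenophase required with a plain summary table")
    states <- summary
  }
  alpha <- dplyr::filter(states, .data$quantity == "alpha")
  obs <- resolve_observations(observations, phenophase, precedence)
  joined <- dplyr::inner_join(obs, alpha, by = "year")
  if (nrow(joined) == 0) abort("no observed years overlap the summary")
  mean(joined$doy >= joined$lo95 & joined$doy <= joined$hi95)
}

#' Compare two fitted summaries of the same phenophase
#'
#' Contrast fits driven by two different temperature stations: per-year
#' differences (a minus b) of the posterior median true date over the
#' overlapping years, plus deltas of the pooled coefficient summaries.
#' When the stations differ by an additive temperature offset, the
#' intercepts absorb it and the true-date medians stay close.
#'
#' @param summary_a,summary_b `pheno_summary` objects (or state tibbles).
#' @return A list with tibbles `alpha` (`year, median_a, median_b, delta`)
#'   and `coefficients` (`quantity, median_a, median_b, delta`; empty when
#'   plain tibbles were given).
#' @export
compare_stations <- function(summary_a, summary_b) {
  states_of <- function(s) if (inherits(s, "pheno_summary")) s$states else s
  a <- dplyr::filter(states_of(summary_a), .data$quantity == "alpha")
  b <- dplyr::filter(states_of(summary_b), .data$quantity == "alpha")
  alpha <- dplyr::inner_join(
    dplyr::select(a, "year", median_a = "median"),
    dplyr::select(b, "year", median_b = "median"),
    by = "year"
  ) |>
    dplyr::mutate(delta = .data$median_a - .data$median_b)
  if (nrow(alpha) == 0) abort("no overlapping years between the summaries")
  coefficients <- tibble::tibble(quantity = character(), median_a = numeric(),
                                 median_b = numeric(), delta = numeric())
  if (inherits(summary_a, "pheno_summary") && inherits(summary_b, "pheno_summary")) {
    ca <- dplyr::filter(summary_a$coefficients, .data$flavour == "pooled")
    cb <- dplyr::filter(summary_b$coefficients, .data$flavour == "pooled")
    coefficients <- dplyr::inner_join(
      dplyr::select(ca, "quantity", median_a = "median"),
      dplyr::select(cb, "quantity", median_b = "median"),
      by = "quantity"
    ) |>
      dplyr::mutate(delta = .data$median_a - .data$median_b)
  }
  list(alpha = alpha, coefficients = coefficients)
}
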