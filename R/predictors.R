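#' Convert a calendar date to day of year
#'
#' 1-based ordinal day within its year (1 January = 1), the scale on which
#' all phenophase dates are modelled.
#'
#' @param date A `Date` vector (or ISO-8601 character).
#' @return Integer day of year.
#' @export
date_to_doy <- function(date) {
  if (is.character(date)) date <- parse_iso_dates(date)
  as.integer(format(date, "%j"))
}

#' Convert (year, day of year) back to a calendar date
#'
#' Inverse of [date_to_doy()]; round-trips exactly.
#'
#' @param year Integer calendar year.
#' @param doy Integer day of year, 1-based; 366 only in leap years.
#' @return A `Date` vector.
#' @export
doy_to_date <- function(year, doy) {
  n_days <- ifelse(is_leap_year(year), 366L, 365L)
  if (any(doy < 1 | doy > n_days)) {
    abort("doy outside the valid range for its year")
  }
  as.Date(paste0(year, "-01-01")) + (doy - 1)
}

#' Number of days in a predictor window
#'
#' The three temperature windows feeding the flowering models: `winter`
#' (1 December of the previous year through 28/29 February; 90 or 91 days
#' depending on the leap status of `year` itself), `march` (31 days) and
#' `april10` (1-10 April, 10 days).
#'
#' @param year Integer year the window belongs to (the flowering year).
#' @param window One of `"winter"`, `"march"`, `"april10"`.
#' @return Integer day count.
#' @export
window_day_count <- function(year, window) {
  window <- match.arg(window, c("winter", "march", "april10"))
  switch(window,
    winter = ifelse(is_leap_year(year), 91L, 90L),
    march = 31L,
    april10 = 10L
  )
}

# Explicit date sequence of a window; predictors must never read outside it.
window_dates <- function(year, window) {
  window <- match.arg(window, c("winter", "march", "april10"))
  switch(window,
    winter = seq(as.Date(paste0(year - 1, "-12-01")),
                 as.Date(paste0(year, if (is_leap_year(year)) "-02-29" else "-02-28")),
                 by = "day"),
    march = seq(as.Date(paste0(year, "-03-01")),
                as.Date(paste0(year, "-03-31")), by = "day"),
    april10 = seq(as.Date(paste0(year, "-04-01")),
                  as.Date(paste0(year, "-04-10")), by = "day")
  )
}

#' Compute per-year temperature predictors
#'
#' For each requested flowering year `t` computes the three predictors of
#' the phenophase models:
#' \describe{
#'   \item{ex1}{mean daily *minimum* temperature, 1 Dec (t-1) to 28/29 Feb
#'     (t) — the winter chilling window releasing bud endodormancy;}
#'   \item{ex2}{mean daily mean temperature, 1-31 March — heat forcing of
#'     flower-bud growth;}
#'   \item{ex3}{mean daily mean temperature, 1-10 April — heat forcing of
#'     further flower and leaf growth.}
#' }
#' Each predictor is the arithmetic mean of the *present* daily values in
#' its window. A predictor is set to `NA` when the fraction of missing days
#' (absent rows or blank cells) exceeds `missing_tolerance`. Years entirely
#' outside the series simply come back missing, not as an error.
#'
#' @param temps Daily temperature tibble (see [read_temperature_csv()]).
#' @param years Integer vector of flowering years (e.g. `1924:2024`).
#' @param missing_tolerance Maximum tolerated fraction of missing days per
#'   window (default 0.1).
#' @return A tibble with columns `year, ex1, ex2, ex3`.
#' @export
compute_predictors <- function(temps, years, missing_tolerance = 0.1) {
  if (length(years) == 0) abort("no years requested")
  if (is.unsorted(years, strictly = TRUE)) {
    abort("years must be strictly increasing")
  }
  value_for <- function(year, window, column) {
    dates <- window_dates(year, window)
    idx <- match(dates, temps$date)
    vals <- temps[[column]][idx] # NA where the date is absent
    frac_missing <- mean(is.na(vals))
    if (frac_missing > missing_tolerance) return(NA_real_)
    mean(vals, na.rm = TRUE)
  }
  tibble::tibble(
    year = as.integer(years),
    ex1 = vapply(years, value_for, numeric(1), window = "winter", column = "tmin_c"),
    ex2 = vapply(years, value_for, numeric(1), window = "march", column = "tmean_c"),
    ex3 = vapply(years, value_for, numeric(1), window = "april10", column = "tmean_c")
  )
}
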