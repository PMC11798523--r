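#' Read a daily air-temperature CSV
#'
#' Reads a station export of daily minimum and daily mean air temperature.
#' The expected dialect is comma-separated UTF-8 with a header row and
#' ISO-8601 dates; blank temperature cells are missing values and are kept
#' missing (never imputed to zero). Rows must be strictly increasing in date
#' and temperatures, when present, must lie in a plausible range of
#' -50 to 50 degrees C.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping the roles `date`, `tmin`,
#'   `tmean` to column names in the file. Defaults to
#'   `c(date = "date", tmin = "tmin_c", tmean = "tmean_c")`.
#' @param station_id Optional station label attached to the result as the
#'   `station_id` attribute.
#'
#' @return A tibble with columns `date` (Date), `tmin_c`, `tmean_c`
#'   (double, degrees C, `NA` where the record is missing).
#' @export
read_temperature_csv <- function(path,
                                 schema = c(date = "date", tmin = "tmin_c",
                                            tmean = "tmean_c"),
                                 station_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  for (role in c("date", "tmin", "tmean")) {
    if (!schema[[role]] %in% names(raw)) {
      abort(paste0("column '", schema[[role]], "' (", role, ") not found in ", path))
    }
  }
  dates <- parse_iso_dates(raw[[schema[["date"]]]])
  out <- tibble::tibble(
    date = dates,
    tmin_c = parse_temperature(raw[[schema[["tmin"]]]], "tmin"),
    tmean_c = parse_temperature(raw[[schema[["tmean"]]]], "tmean")
  )
  if (anyDuplicated(out$date) || is.unsorted(out$date, strictly = TRUE)) {
    abort("dates must be strictly increasing with no duplicates")
  }
  attr(out, "station_id") <- station_id
  out
}

# Strict ISO-8601 parsing: impossible dates like 1924-02-30 slip through
# as.Date on some platforms, so round-trip the parse to catch them.
parse_iso_dates <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) | format(d, "%Y-%m-%d") != x
  if (any(bad)) {
    row <- which(bad)[1]
    abort(paste0("malformed date '", x[row], "' at data row ", row))
  }
  d
}

parse_temperature <- function(x, what) {
  blank <- is.na(x) | trimws(x) == ""
  v <- suppressWarnings(as.numeric(x))
  bad_num <- !blank & is.na(v)
  if (any(bad_num)) {
    row <- which(bad_num)[1]
    abort(paste0("non-numeric ", what, " '", x[row], "' at data row ", row))
  }
  oob <- !is.na(v) & (v < -50 | v > 50)
  if (any(oob)) {
    row <- which(oob)[1]
    abort(paste0(what, " ", v[row], " C at data row ", row,
                 " outside plausible bounds [-50, 50]"))
  }
  v
}

#' Write a daily air-temperature CSV
#'
#' Temperatures are written at 0.1 degree C precision (station-export
#' convention); internal computation always uses full precision.
#'
#' @param temps Tibble as returned by [read_temperature_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(temps, path) {
  out <- tibble::tibble(
    date = format(temps$date, "%Y-%m-%d"),
    tmin_c = round(temps$tmin_c, 1),
    tmean_c = round(temps$tmean_c, 1)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a phenology observation CSV
#'
#' Each row records one observed phenophase date: calendar `year`,
#' `phenophase` (one of FFL, FFB, LFB, LFL; case-insensitive on input),
#' `doy` (1-based day of year) and a `source` label (e.g. website,
#' municipal, private, literature, photograph). Conflicting rows for the
#' same (year, phenophase) from *different* sources are retained — the
#' fitting layer resolves them via [resolve_observations()] — but duplicate
#' (year, phenophase, source) rows are an error.
#'
#' @param path Path to a CSV file with columns `year,phenophase,doy,source`.
#' @return A tibble with columns `year` (int), `phenophase` (chr), `doy`
#'   (int), `source` (chr).
#' @export
read_observations_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    phenophase = readr::col_character(),
    doy = readr::col_integer(),
    source = readr::col_character()
  ), progress = FALSE)
  validate_observations(raw)
}

validate_observations <- function(obs) {
  needed <- c("year", "phenophase", "doy", "source")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols)) {
    abort(paste0("observation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  obs <- tibble::as_tibble(obs[needed])
  obs$phenophase <- toupper(obs$phenophase)
  unknown <- setdiff(unique(obs$phenophase), PHENOPHASES)
  if (length(unknown)) {
    abort(paste0("unknown phenophase label(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(obs$doy < 1 | obs$doy > 366)) abort("doy must lie in [1, 366]")
  bad_366 <- obs$doy == 366 & !is_leap_year(obs$year)
  if (any(bad_366)) {
    abort(paste0("doy 366 in non-leap year ", obs$year[which(bad_366)[1]]))
  }
  key <- paste(obs$year, obs$phenophase, obs$source)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (year, phenophase, source) row: ",
                 key[which(duplicated(key))[1]]))
  }
  obs
}

#' Write a phenology observation CSV
#' @param obs Observation tibble (see [read_observations_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(obs, path) {
  readr::write_csv(validate_observations(obs), path, na = "", progress = FALSE)
  invisible(path)
}

#' Default observation-source precedence
#'
#' When several sources report the same (year, phenophase), the fitting
#' layer keeps exactly one value per year, chosen by this ordering (highest
#' first): contemporaneous website records, municipal unpublished data,
#' private collections, then literature and photographs. Sources not listed
#' rank below all listed ones.
#'
#' @return Character vector of source labels, highest precedence first.
#' @export
default_source_precedence <- function() {
  c("website", "municipal", "private", "literature", "photograph")
}

#' Resolve conflicting observations to one value per year
#'
#' @param obs Observation tibble.
#' @param phenophase Single phenophase label to keep.
#' @param precedence Character vector of source labels, highest first; see
#'   [default_source_precedence()].
#' @return Tibble with columns `year`, `doy`, `source`, one row per year.
#' @export
resolve_observations <- function(obs, phenophase,
                                 precedence = default_source_precedence()) {
  phenophase <- match.arg(toupper(phenophase), PHENOPHASES)
  obs <- validate_observations(obs)
  obs <- obs[obs$phenophase == phenophase, , drop = FALSE]
  if (nrow(obs) == 0) {
    return(tibble::tibble(year = integer(), doy = integer(), source = character()))
  }
  rank <- match(obs$source, precedence)
  rank[is.na(rank)] <- length(precedence) + 1L
  obs$.rank <- rank
  picked <- obs |>
    dplyr::group_by(.data$year) |>
    dplyr::arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  ties <- obs |>
    dplyr::count(.data$year, .data$.rank) |>
    dplyr::semi_join(picked, by = c("year", ".rank")) |>
    dplyr::filter(.data$n > 1)
  if (nrow(ties) > 0) {
    warn(paste0("tied source precedence in year(s) ",
                paste(ties$year, collapse = ", "),
                "; keeping the first record in file order"))
  }
  picked |>
    dplyr::select("year", "doy", "source") |>
    dplyr::arrange(.data$year)
}

#' Write a per-year state summary CSV
#'
#' One row per (year, quantity) with the posterior median and central 95%
#' credible bounds, quantity one of `alpha` (true phenophase date), `mu`
#' (intercept), `beta`, `gamma` (temperature coefficients).
#'
#' @param summary A `pheno_summary` (from [summarize_posterior()]) or a
#'   tibble with columns `year,quantity,median,lo95,hi95`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_summary_csv <- function(summary, path) {
  states <- if (inherits(summary, "pheno_summary")) summary$states else summary
  needed <- c("year", "quantity", "median", "lo95", "hi95")
  if (!all(needed %in% names(states))) {
    abort("state summary needs columns year, quantity, median, lo95, hi95")
  }
  if (nrow(states) == 0) abort("refusing to write an empty state summary")
  readr::write_csv(states[needed], path, progress = FALSE)
  invisible(path)
}

#' Read a per-year state summary CSV
#' @param path Path written by [write_state_summary_csv()].
#' @return Tibble with columns `year,quantity,median,lo95,hi95`.
#' @export
read_state_summary_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    quantity = readr::col_character(),
    median = readr::col_double(),
    lo95 = readr::col_double(),
    hi95 = readr::col_double()
  ), progress = FALSE)
}

#' Write posterior draws as a long CSV
#'
#' Long format `chain,iteration,parameter,value`. By default only the
#' variance parameters are written; per-year latent states can be requested
#' but produce large files (draws x years rows per quantity).
#'
#' @param fit A `pheno_fit` from [sample_posterior()].
#' @param path Output path.
#' @param parameters `"variances"` (default), `"all"`, or a character vector
#'   of parameter names such as `"sigma_phi"` or `"alpha[1989]"`.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path, parameters = "variances") {
  long <- draws_long(fit)
  if (identical(parameters, "variances")) {
    long <- long[grepl("^sigma_", long$parameter), , drop = FALSE]
  } else if (!identical(parameters, "all")) {
    long <- long[long$parameter %in% parameters, , drop = FALSE]
    if (nrow(long) == 0) abort("no draws match the requested parameters")
  }
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read posterior draws from a long CSV
#' @param path Path written by [write_draws_csv()].
#' @return Tibble with columns `chain,iteration,parameter,value`.
#' @export
read_draws_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, col_types = readr::cols(
    chain = readr::col_integer(),
    iteration = readr::col_integer(),
    parameter = readr::col_character(),
    value = readr::col_double()
  ), progress = FALSE)
}
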