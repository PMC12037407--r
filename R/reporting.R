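#' Round half away from zero
#'
#' Reporting-boundary rounding: halves round away from zero (2.5 -> 3,
#' -8.5 -> -9), unlike [round()]'s round-half-to-even.  Internal pipeline
#' values always keep full precision; this is applied only when rendering
#' headline statistics.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Scenario death-count series
#'
#' Deaths (in millions) per year and endpoint for one scenario, anchored to
#' a baseline year against which percent changes are computed.
#'
#' @param scenario_id Scenario label.
#' @param values Data frame with columns `year`, `endpoint`, `value`
#'   (deaths, millions; `>= 0`).
#' @param baseline_year Baseline year; must be present in `values`.
#' @return An object of class `scenario_series` (a tibble with attributes).
#' @export
scenario_series <- function(scenario_id, values, baseline_year = 2010L) {
  values <- tibble::as_tibble(values)
  if (!all(c("year", "endpoint", "value") %in% names(values))) {
    abort("`values` needs columns year, endpoint, value.",
          class = "pmburden_validation_error")
  }
  if (any(values$value < 0)) {
    abort("Series values must be >= 0.", class = "pmburden_validation_error")
  }
  if (!baseline_year %in% values$year) {
    abort(sprintf("Baseline year %d absent from series.", baseline_year),
          class = "pmburden_validation_error")
  }
  structure(values, scenario_id = as.character(scenario_id),
            baseline_year = as.integer(baseline_year),
            class = c("scenario_series", class(values)))
}

series_value <- function(series, endpoint, year) {
  v <- series$value[series$endpoint == endpoint & series$year == year]
  if (length(v) != 1L) {
    abort(sprintf("Series has no unique value for (%s, %d).",
                  endpoint, year),
          class = "pmburden_range_error")
  }
  v
}

#' Percent change versus the baseline year
#'
#' `round(100 * (v_year - v_baseline) / v_baseline)` to the nearest integer
#' percent, half away from zero.  Reductions are negative; render their
#' magnitude as a "reduction" in prose.
#'
#' @param series A [scenario_series()].
#' @param endpoint Endpoint label.
#' @param year Year to compare against the baseline.
#' @return Signed integer percent.
#' @export
percent_change_vs_baseline <- function(series, endpoint, year) {
  base <- series_value(series, endpoint, attr(series, "baseline_year"))
  if (base <= 0) {
    abort("Baseline value must be positive.", class = "pmburden_domain_error")
  }
  v <- series_value(series, endpoint, year)
  round_half_away(100 * (v - base) / base)
}

#' Multi-year average deaths
#'
#' Arithmetic mean of the listed years' values (equal weights), reported to
#' two decimals (millions).
#'
#' @param series A [scenario_series()].
#' @param endpoint Endpoint label.
#' @param years Years to average (default 2020, 2030, 2040, 2049).
#' @return Mean deaths in millions, rounded to 2 decimals.
#' @export
annual_average <- function(series, endpoint,
                           years = c(2020L, 2030L, 2040L, 2049L)) {
  vals <- vapply(years, function(y) series_value(series, endpoint, y),
                 numeric(1))
  round_half_away(mean(vals), 2)
}

#' Nonlinear-versus-linear pathway delta
#'
#' Signed percent difference of the nonlinear pathway's multi-year average
#' total relative to the linear pathway's, over the same years.
#'
#' @param lin,nonlin [scenario_series()] with a `"total"` endpoint.
#' @param years Years to average (default 2020, 2030, 2040, 2049).
#' @param endpoint Endpoint compared (default `"total"`).
#' @return Signed integer percent.
#' @export
linear_vs_nonlinear_delta <- function(lin, nonlin,
                                      years = c(2020L, 2030L, 2040L, 2049L),
                                      endpoint = "total") {
  avg <- function(s) mean(vapply(years, function(y)
    series_value(s, endpoint, y), numeric(1)))
  a_lin <- avg(lin)
  if (a_lin <= 0) {
    abort("Linear average must be positive.", class = "pmburden_domain_error")
  }
  round_half_away(100 * (avg(nonlin) - a_lin) / a_lin)
}

#' Share of one cause in a set of causes
#'
#' `100 * numerator / sum(denominator_set)`, rounded to the nearest integer
#' percent.
#'
#' @param values Named numeric vector of death counts for one year.
#' @param numerator Name of the numerator endpoint.
#' @param denominator_set Names of the endpoints summed in the denominator.
#' @return Integer percent.
#' @export
cause_share <- function(values, numerator, denominator_set) {
  missing <- setdiff(c(numerator, denominator_set), names(values))
  if (length(missing)) {
    abort(sprintf("`values` lacks: %s.", paste(missing, collapse = ", ")),
          class = "pmburden_validation_error")
  }
  denom <- sum(values[denominator_set])
  if (denom <= 0) {
    abort("Denominator sum must be positive.",
          class = "pmburden_domain_error")
  }
  round_half_away(100 * values[[numerator]] / denom)
}

#' Difference between two years of a series
#'
#' `v(year_a) - v(year_b)`, full precision (millions).  With `year_a` the
#' baseline and `year_b` a later year, a positive value is the absolute
#' decrease in deaths.
#'
#' @param series A [scenario_series()].
#' @param endpoint Endpoint label.
#' @param year_a,year_b Years, both present in the series.
#' @return Deaths difference, millions.
#' @export
scenario_difference <- function(series, endpoint, year_a, year_b) {
  series_value(series, endpoint, year_a) -
    series_value(series, endpoint, year_b)
}

#' Decompose a burden reduction across sources
#'
#' Per source, the reduction `delta = deaths_start - deaths_end` and its
#' share of the total four-source reduction.  Shares sum to 1.
#'
#' @param burden_start,burden_end Either burden tibbles from
#'   [source_attributable_deaths()] (the national `linear_total` rows are
#'   used) or named numeric vectors of per-source deaths.
#' @return Tibble with columns `source`, `delta`, `share`.
#' @export
source_reduction_decomposition <- function(burden_start, burden_end) {
  d0 <- source_totals(burden_start)
  d1 <- source_totals(burden_end)
  srcs <- intersect(names(d0), names(d1))
  if (length(srcs) < 1L) {
    abort("No common sources between the two burden tables.",
          class = "pmburden_validation_error")
  }
  delta <- d0[srcs] - d1[srcs]
  total <- sum(delta)
  if (total <= 0) {
    abort("No net reduction to decompose (sum of deltas <= 0).",
          class = "pmburden_domain_error")
  }
  tibble::tibble(source = srcs, delta = as.numeric(delta),
                 share = as.numeric(delta) / total)
}

# named per-source national totals from a burden tibble or named vector
source_totals <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  x <- tibble::as_tibble(x)
  sub <- x[x$endpoint == "linear_total" & x$region == "all", ]
  if (nrow(sub) == 0L) {
    abort("Burden table has no national `linear_total` rows.",
          class = "pmburden_validation_error")
  }
  setNames(sub$deaths, sub$source)
}

#' Read the bundled scenario-deaths fixture table
#'
#' A transcription of published scenario death counts (millions) by model
#' pathway (`linear`/`nonlinear`), endpoint, scenario (`HIST`, `CLE`,
#' `MFR`) and year, used by the reporting stage.
#'
#' @param path CSV path; default the bundled fixture.
#' @return Tibble with columns `model`, `endpoint`, `scenario`, `year`,
#'   `deaths_million`.
#' @export
read_table1_fixture <- function(path = system.file(
  "extdata", "table1_fixture.csv", package = "pmburden", mustWork = TRUE)) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("model", "endpoint", "scenario", "year", "deaths_million")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("Fixture needs columns: %s.", paste(need, collapse = ", ")),
          class = "pmburden_format_error")
  }
  tbl
}

#' Build a scenario series from the fixture table
#'
#' Assembles one pathway's series for one future scenario, prepending the
#' historical 2010 baseline column so percent changes against 2010 are
#' available.
#'
#' @param fixture Tibble from [read_table1_fixture()].
#' @param model `"linear"` or `"nonlinear"`.
#' @param scenario `"CLE"` or `"MFR"`.
#' @return A [scenario_series()] with baseline year 2010.
#' @export
fixture_scenario_series <- function(fixture, model = c("linear", "nonlinear"),
                                    scenario = c("CLE", "MFR")) {
  model <- match.arg(model)
  scenario <- match.arg(scenario)
  sub <- fixture[fixture$model == model &
                   fixture$scenario %in% c("HIST", scenario), ]
  scenario_series(
    scenario,
    tibble::tibble(year = sub$year, endpoint = sub$endpoint,
                   value = sub$deaths_million),
    baseline_year = 2010L)
}
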