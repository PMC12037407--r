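#' Endpoint specification for a burden computation
#'
#' Binds a mortality endpoint to the kind of exposure-response function used
#' for it and the age groups it applies to.  GEMM causes default to adults
#' (25+), the convention of the hazard-ratio framework they come from; the
#' linear all-cause pathway defaults to all ages.
#'
#' @param endpoint One of `"all_cause_chronic"`, `"all_cause_acute"`,
#'   `"LC"`, `"COPD"`, `"IHD"`, `"stroke"`, `"LRI"`, `"NCD_LRI"`.
#' @param erf_kind `"linear"` or `"gemm"`.
#' @param applicable_ages Age-group labels the endpoint applies to;
#'   `NULL` (default) resolves to 25+ for GEMM and all ages for linear.
#' @return An object of class `endpoint_spec`.
#' @export
endpoint_spec <- function(endpoint, erf_kind = c("linear", "gemm"),
                          applicable_ages = NULL) {
  endpoint <- match.arg(endpoint, burden_endpoints)
  erf_kind <- match.arg(erf_kind)
  all_groups <- age_group_labels()
  if (is.null(applicable_ages)) {
    applicable_ages <- if (erf_kind == "gemm") {
      all_groups[match("25-29", all_groups):length(all_groups)]
    } else {
      all_groups
    }
  }
  if (!all(applicable_ages %in% all_groups)) {
    abort("Unknown age group in `applicable_ages`.",
          class = "pmburden_validation_error")
  }
  structure(list(endpoint = endpoint, erf_kind = erf_kind,
                 applicable_ages = applicable_ages),
            class = "endpoint_spec")
}

# rates for (endpoint, ages), erroring on a missing row
baseline_rates <- function(base, endpoint, ages) {
  base <- as_baseline_mortality(base)
  sub <- base[base$endpoint == endpoint, ]
  rates <- sub$rate[match(ages, sub$age_group)]
  if (anyNA(rates)) {
    missing <- ages[is.na(rates)][1L]
    abort(sprintf("Baseline mortality lacks a row for (%s, %s).",
                  endpoint, missing),
          class = "pmburden_config_error")
  }
  setNames(rates, ages)
}

#' Attributable premature deaths for one endpoint
#'
#' The population-attributable burden
#' `deaths = sum_cells sum_ages pop(cell, age) * rate(endpoint, age) *
#' AF(RR(c(cell)))`, aggregated by region label and in total (region
#' `"all"`).  The relative risk comes from the endpoint's linear or GEMM
#' exposure-response function; the attributable fraction uses the ratio
#' form `(RR-1)/RR` by default (see [attributable_fraction()]).
#'
#' @param conc A [concentration_field()] (or per-cell numeric vector) of
#'   total PM2.5 — or of one source's contribution for source burdens.
#' @param pop A [population_grid()] aligned with `conc`.
#' @param base Baseline-mortality table with rows for the endpoint and every
#'   applicable age group.
#' @param spec An [endpoint_spec()].
#' @param erf A [linear_erf()] (for `erf_kind = "linear"`) or
#'   [gemm_params()] (for `"gemm"`).
#' @param af_form `"ratio"` (default) or `"delta"`.
#' @return A tibble with columns `region` and `deaths` (persons/yr); the
#'   `"all"` row is the sum over regions.
#' @export
#' @examples
#' g <- grid_spec(1, 1)
#' conc <- concentration_field(g, 10, "total_pm25", "CLE", 2010)
#' counts <- matrix(0, 1, 18); counts[1, 9] <- 1e6  # all in ages 40-44
#' pop <- population_grid(g, counts, year = 2010)
#' base <- tibble::tibble(endpoint = "all_cause_chronic",
#'                        age_group = age_group_labels(), rate = 0.01)
#' spec <- endpoint_spec("all_cause_chronic", "linear")
#' attributable_deaths(conc, pop, base, spec, linear_erf(),
#'                     af_form = "delta")  # 800 deaths
attributable_deaths <- function(conc, pop, base, spec, erf,
                                af_form = c("ratio", "delta")) {
  af_form <- match.arg(af_form)
  stopifnot(inherits(pop, "population_grid"),
            inherits(spec, "endpoint_spec"))
  if (inherits(conc, "concentration_field")) {
    validate_alignment(list(conc, pop))
    cvals <- conc$values
  } else {
    cvals <- as.numeric(conc)
    if (length(cvals) != nrow(pop$counts)) {
      abort("Concentration vector does not match the population grid.",
            class = "pmburden_alignment_error")
    }
  }
  rates <- baseline_rates(base, spec$endpoint, spec$applicable_ages)
  rr <- switch(spec$erf_kind,
               linear = linear_rr(cvals, erf),
               gemm = gemm_rr(cvals, erf))
  af <- attributable_fraction(rr, form = af_form)
  at_risk <- as.numeric(
    pop$counts[, spec$applicable_ages, drop = FALSE] %*% rates)
  deaths_cell <- af * at_risk
  regions <- pop$grid$region_labels
  by_region <- tapply(deaths_cell, regions, sum)
  tibble::tibble(
    region = c(names(by_region), "all"),
    deaths = c(as.numeric(by_region), sum(deaths_cell)))
}

# national ("all"-region) death count from an attributable_deaths() result
national_deaths <- function(tbl) {
  tbl$deaths[tbl$region == "all"]
}

#' Combined linear-pathway deaths
#'
#' Total premature deaths in the linear pathway: acute (short-term) plus
#' chronic (long-term) deaths.
#'
#' @param acute,chronic Non-negative death counts.
#' @return Their sum.
#' @export
linear_total_deaths <- function(acute, chronic) {
  if (any(acute < 0) || any(chronic < 0)) {
    abort("Death counts must be >= 0.", class = "pmburden_domain_error")
  }
  acute + chronic
}

#' Combined nonlinear-pathway deaths
#'
#' Two totalization conventions exist for the GEMM pathway: summing the
#' five cause-specific burdens (lung cancer, COPD, ischemic heart disease,
#' stroke, lower respiratory infections), or evaluating a single joint
#' hazard function for non-communicable disease plus LRI (`NCD_LRI`).
#' Both are supported; they generally differ because the joint curve is not
#' the sum of the cause curves.
#'
#' @param cause_deaths Named numeric vector of death counts; must contain
#'   the five causes for `mode = "sum_causes"`, or `NCD_LRI` for
#'   `mode = "ncd_lri"`.
#' @param mode `"sum_causes"` (default) or `"ncd_lri"`.
#' @return Total deaths.
#' @export
nonlinear_total_deaths <- function(cause_deaths,
                                   mode = c("sum_causes", "ncd_lri")) {
  mode <- match.arg(mode)
  need <- if (mode == "sum_causes") {
    c("LC", "COPD", "IHD", "stroke", "LRI")
  } else {
    "NCD_LRI"
  }
  missing <- setdiff(need, names(cause_deaths))
  if (length(missing)) {
    abort(sprintf("`cause_deaths` lacks: %s.",
                  paste(missing, collapse = ", ")),
          class = "pmburden_config_error")
  }
  sum(cause_deaths[need])
}

#' Source-attributable deaths via the linear pathway
#'
#' Evaluates the linear acute and chronic all-cause burden on each source's
#' concentration field, the convention for source attribution (the GEMM
#' curve is not applied to source fields by default because a nonlinear
#' function of a concentration fraction has no attributable-burden
#' interpretation; set `allow_gemm`-style analyses up manually if wanted).
#' With `af_form = "delta"` the per-source burdens are exactly additive:
#' they sum to the burden of the summed source fields.
#'
#' @param sources Named list of per-cell concentration vectors (names among
#'   `re`, `bi`, `in`, `tr`), e.g. from [apportion_suite()].
#' @param pop A [population_grid()].
#' @param base Baseline-mortality table.
#' @param chronic_erf,acute_erf [linear_erf()]s (defaults: WHO 1.08 chronic;
#'   placeholder acute).
#' @param af_form `"ratio"` or `"delta"` (default `"delta"`, the additive
#'   choice natural for decomposing a total across sources).
#' @param scenario_id,year Metadata stamped on the output rows.
#' @return A burden tibble with columns `scenario_id`, `year`, `endpoint`
#'   (`all_cause_acute`, `all_cause_chronic`, `linear_total`), `source`,
#'   `region`, `deaths`.
#' @export
source_attributable_deaths <- function(sources, pop, base,
                                       chronic_erf = linear_erf(),
                                       acute_erf = acute_linear_erf(),
                                       af_form = "delta",
                                       scenario_id = NA_character_,
                                       year = NA_integer_) {
  bad <- setdiff(names(sources), c(pm_sources, "secondary"))
  if (length(bad)) {
    abort(sprintf("Unknown source(s): %s.", paste(bad, collapse = ", ")),
          class = "pmburden_validation_error")
  }
  sources <- sources[intersect(pm_sources, names(sources))]
  if (!length(sources)) {
    abort("No source fields present.", class = "pmburden_config_error")
  }
  out <- list()
  for (src in names(sources)) {
    cvals <- pmax(as.numeric(sources[[src]]), 0)  # risk model needs c >= 0
    ac <- attributable_deaths(cvals, pop, base,
                              endpoint_spec("all_cause_acute", "linear"),
                              acute_erf, af_form = af_form)
    ch <- attributable_deaths(cvals, pop, base,
                              endpoint_spec("all_cause_chronic", "linear"),
                              chronic_erf, af_form = af_form)
    tot <- ac
    tot$deaths <- linear_total_deaths(ac$deaths, ch$deaths)
    for (piece in list(list("all_cause_acute", ac),
                       list("all_cause_chronic", ch),
                       list("linear_total", tot))) {
      out <- c(out, list(tibble::tibble(
        scenario_id = scenario_id, year = year, endpoint = piece[[1L]],
        source = src, region = piece[[2L]]$region,
        deaths = piece[[2L]]$deaths)))
    }
  }
  dplyr::bind_rows(out)
}
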