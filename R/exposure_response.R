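#' Linear all-cause exposure-response function
#'
#' The linear pathway assumes relative risk rises in a straight line with
#' annual-mean PM2.5: `RR = 1 + (rr_per_10 - 1) * max(0, c - counterfactual) / 10`.
#' The chronic (long-term) default is the WHO-recommended all-cause relative
#' risk of 1.08 per 10 ug/m3.  The acute (short-term) coefficient is not an
#' established constant here: its default 1.0096 is a structural placeholder
#' chosen so acute deaths are about 11% of the combined linear total, and
#' should be replaced by the user's own short-term coefficient for
#' substantive work.
#'
#' @param rr_per_10 Relative risk at +10 ug/m3 (>= 1); default 1.08.
#' @param endpoint `"all_cause_chronic"` or `"all_cause_acute"`.
#' @param counterfactual Concentration (ug/m3) below which no excess risk is
#'   attributed; default 0.
#' @return An object of class `linear_erf`.
#' @export
linear_erf <- function(rr_per_10 = 1.08, endpoint = "all_cause_chronic",
                       counterfactual = 0) {
  endpoint <- match.arg(endpoint, c("all_cause_chronic", "all_cause_acute"))
  if (!is.numeric(rr_per_10) || length(rr_per_10) != 1L || rr_per_10 < 1) {
    abort("`rr_per_10` must be a scalar >= 1.", class = "pmburden_domain_error")
  }
  if (!is.numeric(counterfactual) || counterfactual < 0) {
    abort("`counterfactual` must be >= 0.", class = "pmburden_domain_error")
  }
  structure(list(rr_per_10 = rr_per_10, endpoint = endpoint,
                 counterfactual = counterfactual),
            class = "linear_erf")
}

#' Default acute (short-term) linear ERF
#'
#' Placeholder short-term coefficient 1.0096 per 10 ug/m3 (see
#' [linear_erf()] for its rationale).
#' @return A `linear_erf` for endpoint `all_cause_acute`.
#' @export
acute_linear_erf <- function() {
  linear_erf(rr_per_10 = 1.0096, endpoint = "all_cause_acute")
}

#' GEMM hazard-ratio parameters for one cause
#'
#' Parameters of the Global Exposure Mortality Model hazard-ratio function
#' (see [gemm_rr()]): shape `theta` (dimensionless) and `alpha`, `mu`, `nu`
#' (ug/m3), with a counterfactual cut-off below which no excess risk is
#' attributed (default 2.4 ug/m3).
#'
#' @param endpoint Cause label (e.g. `"IHD"`, `"NCD_LRI"`).
#' @param theta,alpha,mu,nu GEMM curve parameters; `theta >= 0`,
#'   `alpha > 0`, `nu > 0`.
#' @param counterfactual Cut-off concentration in ug/m3 (default 2.4).
#' @param age_group Age-group label or `"adult_25plus"` (default) when a
#'   single adult curve is used.
#' @return An object of class `gemm_params`.
#' @export
gemm_params <- function(endpoint, theta, alpha, mu, nu,
                        counterfactual = 2.4, age_group = "adult_25plus") {
  if (!is.numeric(theta) || theta < 0 || !is.finite(theta)) {
    abort("`theta` must be finite and >= 0.", class = "pmburden_domain_error")
  }
  if (alpha <= 0 || nu <= 0 || counterfactual < 0) {
    abort("Require alpha > 0, nu > 0, counterfactual >= 0.",
          class = "pmburden_domain_error")
  }
  structure(list(endpoint = as.character(endpoint), theta = theta,
                 alpha = alpha, mu = mu, nu = nu,
                 counterfactual = counterfactual,
                 age_group = as.character(age_group)),
            class = "gemm_params")
}

#' GEMM relative risk
#'
#' The Global Exposure Mortality Model hazard-ratio function.  With
#' `z = max(0, c - counterfactual)`,
#' \deqn{RR(c) = \exp\left\{\theta \,
#'   \frac{\ln(z/\alpha + 1)}{1 + \exp(-(z - \mu)/\nu)}\right\}}
#' (natural logarithm).  The curve rises steeply at low concentrations and
#' flattens at high ones; `RR = 1` exactly for concentrations at or below
#' the counterfactual.
#'
#' @param c Concentration(s), ug/m3, finite and >= 0 (vectorized).
#' @param p A [gemm_params()].
#' @return Relative risk(s), `>= 1`.
#' @export
#' @examples
#' p <- gemm_params("NCD_LRI", theta = 0.1430, alpha = 1.6, mu = 15.5, nu = 36.8)
#' gemm_rr(2.4, p)   # 1: at the counterfactual
#' gemm_rr(12.4, p)  # about 1.140
gemm_rr <- function(c, p) {
  if (!inherits(p, "gemm_params")) {
    abort("`p` must be gemm_params.", class = "pmburden_validation_error")
  }
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0)) {
    abort("Concentrations must be finite and >= 0.",
          class = "pmburden_domain_error")
  }
  z <- pmax(0, c - p$counterfactual)
  exp(p$theta * log(z / p$alpha + 1) / (1 + exp(-(z - p$mu) / p$nu)))
}

#' Linear relative risk
#'
#' `RR = 1 + (rr_per_10 - 1) * max(0, c - counterfactual) / 10`.
#'
#' @param c Concentration(s), ug/m3, finite and >= 0 (vectorized).
#' @param erf A [linear_erf()].
#' @return Relative risk(s), `>= 1`.
#' @export
#' @examples
#' linear_rr(10, linear_erf())  # 1.08
linear_rr <- function(c, erf) {
  if (!inherits(erf, "linear_erf")) {
    abort("`erf` must be a linear_erf.", class = "pmburden_validation_error")
  }
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0)) {
    abort("Concentrations must be finite and >= 0.",
          class = "pmburden_domain_error")
  }
  1 + (erf$rr_per_10 - 1) * pmax(0, c - erf$counterfactual) / 10
}

#' Attributable fraction from a relative risk
#'
#' Share of baseline deaths attributable to the exposure.  The default
#' ratio form `AF = (RR - 1) / RR` is bounded in `[0, 1)`; the `delta`
#' form `AF = RR - 1` is the strictly proportional alternative, under which
#' linear-pathway burdens are exactly additive across sources.
#'
#' @param rr Relative risk(s), `>= 1`.
#' @param form `"ratio"` (default) or `"delta"`.
#' @return Attributable fraction(s).
#' @export
#' @examples
#' attributable_fraction(1.25)            # 0.2
#' attributable_fraction(1.25, "delta")   # 0.25
attributable_fraction <- function(rr, form = c("ratio", "delta")) {
  form <- match.arg(form)
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr < 1)) {
    abort("Relative risks must be finite and >= 1.",
          class = "pmburden_domain_error")
  }
  if (form == "ratio") (rr - 1) / rr else rr - 1
}

#' Read a GEMM parameter CSV
#'
#' Columns: `endpoint`, `age_group`, `theta`, `alpha`, `mu`, `nu`,
#' `counterfactual`.  The package ships
#' `system.file("extdata", "gemm_params_synthetic.csv", package = "pmburden")`,
#' a plausible editable parameter set (the NCD_LRI adult row is the declared
#' fixture theta=0.1430, alpha=1.6, mu=15.5, nu=36.8); substitute a
#' transcription of the published GEMM fit for substantive work.
#'
#' @param path CSV path.
#' @return Named list of [gemm_params()], keyed `endpoint` (or
#'   `endpoint:age_group` for age-specific rows).
#' @export
read_gemm_params <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("endpoint", "age_group", "theta", "alpha", "mu", "nu",
            "counterfactual")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("GEMM parameter file needs columns: %s.",
                  paste(need, collapse = ", ")),
          class = "pmburden_format_error")
  }
  out <- list()
  for (i in seq_len(nrow(tbl))) {
    p <- gemm_params(tbl$endpoint[i], tbl$theta[i], tbl$alpha[i],
                     tbl$mu[i], tbl$nu[i], tbl$counterfactual[i],
                     tbl$age_group[i])
    key <- if (p$age_group == "adult_25plus") p$endpoint else
      paste(p$endpoint, p$age_group, sep = ":")
    out[[key]] <- p
  }
  out
}

#' Bundled synthetic GEMM parameter set
#'
#' Loads the package's bundled GEMM parameter file (see
#' [read_gemm_params()] for its provenance and caveats).
#' @return Named list of [gemm_params()].
#' @export
default_gemm_params <- function() {
  read_gemm_params(system.file("extdata", "gemm_params_synthetic.csv",
                               package = "pmburden", mustWork = TRUE))
}
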