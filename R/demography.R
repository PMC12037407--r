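#' Age-structure series at anchor years
#'
#' Per-anchor-year shares of the national population in each 5-year age
#' group.  Shares at non-anchor years come from [interpolate_age_shares()].
#'
#' @param anchor_years Ordered integer years.
#' @param shares Numeric matrix, one column per anchor year and one row per
#'   age group (rownames [age_group_labels()]); each column sums to 1
#'   (tolerance 1e-9), entries >= 0.
#' @return An object of class `age_structure`.
#' @export
age_structure <- function(anchor_years, shares) {
  anchor_years <- as.integer(anchor_years)
  shares <- as.matrix(shares)
  if (is.unsorted(anchor_years, strictly = TRUE)) {
    abort("`anchor_years` must be strictly increasing.",
          class = "pmburden_validation_error")
  }
  if (ncol(shares) != length(anchor_years)) {
    abort("One share column per anchor year required.",
          class = "pmburden_validation_error")
  }
  if (nrow(shares) != length(age_group_labels())) {
    abort("Shares must cover the 18 groups \"0-4\" .. \"85+\".",
          class = "pmburden_validation_error")
  }
  if (any(shares < 0)) {
    abort("Shares must be >= 0.", class = "pmburden_validation_error")
  }
  sums <- colSums(shares)
  if (any(abs(sums - 1) > 1e-9)) {
    abort(sprintf("Anchor-year shares must sum to 1 (worst deviation %.3g).",
                  max(abs(sums - 1))),
          class = "pmburden_validation_error")
  }
  rownames(shares) <- age_group_labels()
  colnames(shares) <- anchor_years
  structure(list(anchor_years = anchor_years, shares = shares),
            class = "age_structure")
}

#' Interpolate age-group shares to a given year
#'
#' Componentwise linear interpolation between the bracketing anchor years,
#' followed by renormalization so the interpolated shares sum to exactly 1.
#' No extrapolation: the year must lie within the anchor range.
#'
#' @param s An [age_structure()].
#' @param year Integer year, `min(anchor) <= year <= max(anchor)`.
#' @return Named numeric vector of shares over [age_group_labels()],
#'   summing to 1.
#' @export
interpolate_age_shares <- function(s, year) {
  stopifnot(inherits(s, "age_structure"))
  year <- as.integer(year)
  ys <- s$anchor_years
  if (year < ys[1L] || year > ys[length(ys)]) {
    abort(sprintf("Year %d outside anchor range [%d, %d]; no extrapolation.",
                  year, ys[1L], ys[length(ys)]),
          class = "pmburden_range_error")
  }
  i <- match(year, ys)
  if (!is.na(i)) {
    out <- s$shares[, i]
  } else {
    lo <- max(which(ys < year))
    hi <- lo + 1L
    w <- (year - ys[lo]) / (ys[hi] - ys[lo])
    out <- (1 - w) * s$shares[, lo] + w * s$shares[, hi]
    out <- out / sum(out)
  }
  setNames(as.numeric(out), age_group_labels())
}

#' Population share at or above an age group
#'
#' National fraction of the population in `threshold_group` and all older
#' groups — e.g. the 65+ share with `threshold_group = "65-69"`.
#'
#' @param pop A [population_grid()].
#' @param threshold_group Age-group label marking the lower bound.
#' @return Fraction in `[0, 1]`.
#' @export
share_over_age <- function(pop, threshold_group) {
  stopifnot(inherits(pop, "population_grid"))
  i <- match(threshold_group, pop$age_groups)
  if (is.na(i)) {
    abort(sprintf("Unknown age group `%s`.", threshold_group),
          class = "pmburden_validation_error")
  }
  total <- sum(pop$counts)
  if (total <= 0) {
    abort("Population total is zero.", class = "pmburden_domain_error")
  }
  sum(pop$counts[, i:ncol(pop$counts)]) / total
}

#' Default ageing age-structure series
#'
#' Two anchor pyramids: a young-skewed 2010 structure with the 65+ share at
#' exactly 8%, and an aged 2049 structure with the 65+ share at exactly 23%,
#' with linear share interpolation (then renormalization) in between.  The
#' same structure is intended to serve every emission scenario, so scenario
#' contrasts isolate the effect of concentrations.
#'
#' @return An [age_structure()] anchored at 2010 and 2049.
#' @export
default_age_structure <- function() {
  # relative within-block profiles; blocks rescaled to exact 65+/under-65 totals
  u65_2010 <- c(1.05, 1.00, 1.10, 1.25, 1.30, 1.20, 1.10, 1.05, 1.15,
                1.05, 0.90, 0.70, 0.50)
  o65_2010 <- c(0.40, 0.28, 0.17, 0.10, 0.05)
  u65_2049 <- c(0.55, 0.60, 0.65, 0.70, 0.75, 0.85, 0.95, 1.05, 1.10,
                1.15, 1.20, 1.25, 1.20)
  o65_2049 <- c(0.32, 0.27, 0.20, 0.13, 0.08)
  mk <- function(u65, o65, share65) {
    c(u65 / sum(u65) * (1 - share65), o65 / sum(o65) * share65)
  }
  age_structure(c(2010L, 2049L),
                cbind(mk(u65_2010, o65_2010, 0.08),
                      mk(u65_2049, o65_2049, 0.23)))
}
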