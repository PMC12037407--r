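#' Per-source concentration from a perturbation run pair
#'
#' Brute-force source apportionment: the concentration attributable to the
#' perturbed source is the scaled run difference
#' `(C_NPC - C_PC) / reduction_fraction`.  The scaling assumes the
#' perturbation is small enough to sit in the near-linear regime of the
#' atmospheric chemistry, which is why the default emission reduction is
#' 30% rather than 100%.
#'
#' Cells where the perturbed run exceeds the unperturbed run yield negative
#' contributions.  These are retained (clipping would bias national sums)
#' unless `floor_zero = TRUE`; if the fraction of negative cells exceeds
#' `warn_negative_frac`, a warning is emitted because widespread sign flips
#' signal nonlinear chemistry or a mismatched run pair.
#'
#' @param pair A [source_run_pair()].
#' @param floor_zero If `TRUE`, clip negative cells to zero (default `FALSE`).
#' @param warn_negative_frac Warn when the fraction of negative cells exceeds
#'   this threshold (default 0.05).
#' @return Numeric vector of per-cell source concentrations (ug/m3), with
#'   attribute `source` set to the perturbed source.
#' @export
#' @examples
#' g <- grid_spec(1, 1)
#' npc <- concentration_field(g, 20, "total_pm25", "CLE", 2010)
#' pc <- concentration_field(g, 18.5, "total_pm25", "CLE", 2010, "PC", "bi")
#' source_concentration(source_run_pair(npc, pc, 0.30))  # 5.0
source_concentration <- function(pair, floor_zero = FALSE,
                                 warn_negative_frac = 0.05) {
  if (!inherits(pair, "source_run_pair")) {
    abort("`pair` must be a source_run_pair.",
          class = "pmburden_validation_error")
  }
  if (pair$reduction_fraction <= 0) {
    abort("`reduction_fraction` must be positive.",
          class = "pmburden_domain_error")
  }
  out <- (pair$npc$values - pair$pc$values) / pair$reduction_fraction
  neg_frac <- mean(out < 0)
  if (neg_frac > warn_negative_frac) {
    warn(sprintf(
      "%.1f%% of cells have negative source contributions (source %s): nonlinear chemistry or mismatched runs?",
      100 * neg_frac, pair$pc$perturbed_source),
      class = "pmburden_negative_cells")
  }
  if (floor_zero) out <- pmax(out, 0)
  attr(out, "source") <- pair$pc$perturbed_source
  out
}

#' Primary PM2.5 contribution of a source
#'
#' Cellwise difference of a source's total-PM2.5 contribution and its
#' secondary organic and inorganic parts:
#' `C_primary = C_total - C_SIA - C_SOA`.
#'
#' @param total,sia,soa Aligned per-cell fields ([concentration_field()]s or
#'   bare numeric vectors of equal length).
#' @return Numeric per-cell primary-PM2.5 field.
#' @export
primary_pm_concentration <- function(total, sia, soa) {
  v <- align_values(list(total = total, sia = sia, soa = soa))
  v$total - v$sia - v$soa
}

#' Secondary PM2.5 from the unperturbed run
#'
#' Cellwise sum of the unperturbed run's secondary organic and secondary
#' inorganic aerosol fields: `C_secondary = C_NPC,SOA + C_NPC,SIA`.
#'
#' @param npc_soa,npc_sia Aligned NPC fields ([concentration_field()]s or
#'   numeric vectors of equal length).
#' @return Numeric per-cell secondary-PM2.5 field.
#' @export
secondary_concentration <- function(npc_soa, npc_sia) {
  v <- align_values(list(soa = npc_soa, sia = npc_sia))
  v$soa + v$sia
}

# Extract per-cell values from fields or vectors, enforcing alignment.
align_values <- function(named) {
  fields <- Filter(function(o) inherits(o, "concentration_field"), named)
  if (length(fields) >= 2L) validate_alignment(fields)
  vals <- lapply(named, function(o) {
    if (inherits(o, "concentration_field")) o$values else as.numeric(o)
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("Field lengths differ: %s.",
                  paste(lens, collapse = ", ")),
          class = "pmburden_alignment_error")
  }
  vals
}

#' Apportion a full run suite into per-source concentration sets
#'
#' Convenience wrapper over [source_concentration()]: given the list of
#' fields for one scenario and year (one NPC total-PM2.5 field plus one PC
#' total-PM2.5 field per perturbed source), returns the per-source
#' concentration fields as a named list.
#'
#' @param fields List of [concentration_field()]s for one scenario/year.
#' @param reduction_fraction Emission-reduction fraction of the PC runs.
#' @param floor_zero Passed to [source_concentration()].
#' @return Named list: per-cell numeric fields for each source present,
#'   plus `secondary` when NPC SOA and SIA fields are available.
#' @export
apportion_suite <- function(fields, reduction_fraction = 0.30,
                            floor_zero = FALSE) {
  is_npc <- vapply(fields, function(f) f$run_kind == "NPC", logical(1))
  species <- vapply(fields, `[[`, character(1), "species")
  npc_total <- fields[is_npc & species == "total_pm25"]
  if (length(npc_total) != 1L) {
    abort("Need exactly one NPC total_pm25 field.",
          class = "pmburden_validation_error")
  }
  npc_total <- npc_total[[1L]]
  out <- list()
  for (f in fields[!is_npc]) {
    if (f$species != "total_pm25") next
    pair <- source_run_pair(npc_total, f, reduction_fraction)
    out[[f$perturbed_source]] <-
      source_concentration(pair, floor_zero = floor_zero)
  }
  npc_soa <- fields[is_npc & species == "soa"]
  npc_sia <- fields[is_npc & species == "sia"]
  if (length(npc_soa) == 1L && length(npc_sia) == 1L) {
    out$secondary <- secondary_concentration(npc_soa[[1L]], npc_sia[[1L]])
  }
  out
}
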