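#' Grid specification for a regular concentration raster
#'
#' A `grid_spec` describes the regular row/column raster shared by all gridded
#' objects in a pipeline: its dimensions, the (uniform) cell area, and a
#' per-cell categorical region label used for regional aggregation.  The grid
#' is deliberately abstract — burden arithmetic only ever pairs a cell's
#' concentration with the same cell's population, so no projection or
#' coordinate system is carried.
#'
#' @param n_rows,n_cols Positive integers, raster dimensions.
#' @param cell_area Uniform cell area in km^2 (default 2500, i.e. 50 km x 50 km).
#' @param region_labels Character vector of length `n_rows * n_cols` (row-major)
#'   assigning each cell to exactly one region, or a single label recycled to
#'   every cell.  Default `"domain"`.  The label `"all"` is reserved for the
#'   national-total row of burden tables.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' g <- grid_spec(2, 3)
#' n_cells(g)
grid_spec <- function(n_rows, n_cols, cell_area = 2500,
                      region_labels = "domain") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    abort("`n_rows` and `n_cols` must be positive integers.",
          class = "pmburden_validation_error")
  }
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0) {
    abort("`cell_area` must be a positive scalar (km^2).",
          class = "pmburden_validation_error")
  }
  nc <- n_rows * n_cols
  region_labels <- as.character(region_labels)
  if (any(region_labels == "all")) {
    abort("Region label \"all\" is reserved for national totals.",
          class = "pmburden_validation_error")
  }
  if (length(region_labels) == 1L) region_labels <- rep(region_labels, nc)
  if (length(region_labels) != nc || anyNA(region_labels)) {
    abort(sprintf("`region_labels` must name every one of the %d cells.", nc),
          class = "pmburden_validation_error")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_area = as.numeric(cell_area), region_labels = region_labels),
    class = "grid_spec"
  )
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_rows * grid$n_cols
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("<grid_spec %d x %d, %g km^2/cell, %d region(s)>",
          x$n_rows, x$n_cols, x$cell_area, length(unique(x$region_labels)))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

pm_species <- c("total_pm25", "soa", "sia", "primary_pm25")
pm_sources <- c("re", "bi", "in", "tr")

#' Gridded annual-mean concentration field
#'
#' One species' annual-mean concentration for one scenario, year and model
#' run.  `run_kind` distinguishes the unperturbed reference run (`"NPC"`)
#' from a run in which a single source's emissions were reduced (`"PC"`);
#' a PC field must name the perturbed source.  The species `"sia"` denotes
#' summed secondary inorganic mass (the sulfate, nitrate and ammonium
#' particle families at full particle weight).
#'
#' @param grid A [grid_spec()].
#' @param values Numeric vector or matrix of per-cell concentrations
#'   (ug/m3), length `n_cells(grid)`; all finite and non-negative.
#' @param species One of `"total_pm25"`, `"soa"`, `"sia"`, `"primary_pm25"`.
#' @param scenario_id Scenario label (e.g. `"CLE"`, `"MFR"`).
#' @param year Integer calendar year.
#' @param run_kind `"NPC"` (unperturbed) or `"PC"` (source-perturbed).
#' @param perturbed_source For PC runs one of `"re"`, `"bi"`, `"in"`, `"tr"`
#'   (residential coal heating, biomass burning, industry, on-road tailpipe
#'   transport); must be `"none"` for NPC runs.
#'
#' @return An object of class `concentration_field`.
#' @export
#' @examples
#' g <- grid_spec(2, 2)
#' concentration_field(g, c(10, 12, 8, 9), "total_pm25", "CLE", 2010)
concentration_field <- function(grid, values, species, scenario_id, year,
                                run_kind = "NPC", perturbed_source = "none") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != n_cells(grid)) {
    abort(sprintf("`values` has length %d; grid has %d cells.",
                  length(values), n_cells(grid)),
          class = "pmburden_validation_error")
  }
  bad <- !is.finite(values) | values < 0
  if (any(bad)) {
    abort(sprintf("%d cell(s) have non-finite or negative concentrations.",
                  sum(bad)),
          class = "pmburden_validation_error")
  }
  species <- match.arg(species, pm_species)
  run_kind <- match.arg(run_kind, c("NPC", "PC"))
  perturbed_source <- match.arg(perturbed_source, c(pm_sources, "none"))
  if (run_kind == "NPC" && perturbed_source != "none") {
    abort("An NPC field cannot name a perturbed source.",
          class = "pmburden_validation_error")
  }
  if (run_kind == "PC" && perturbed_source == "none") {
    abort("A PC field must name its perturbed source.",
          class = "pmburden_validation_error")
  }
  structure(
    list(grid = grid, values = values, species = species,
         scenario_id = as.character(scenario_id), year = as.integer(year),
         run_kind = run_kind, perturbed_source = perturbed_source),
    class = "concentration_field"
  )
}

#' @export
format.concentration_field <- function(x, ...) {
  src <- if (x$run_kind == "PC") paste0(" [", x$perturbed_source, "]") else ""
  sprintf("<concentration_field %s %s %d %s%s, mean %.3g ug/m3>",
          x$species, x$scenario_id, x$year, x$run_kind, src, mean(x$values))
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Matched unperturbed/perturbed run pair
#'
#' Pairs an NPC field with the PC field of one perturbed source, together
#' with the fractional emission reduction applied in the PC run.  This is
#' the input to [source_concentration()].
#'
#' @param npc,pc [concentration_field()]s sharing grid, species, scenario
#'   and year; `npc` must be an NPC run and `pc` a PC run.
#' @param reduction_fraction Fractional emission reduction in `(0, 1]`
#'   applied to the perturbed source (default 0.30).
#'
#' @return An object of class `source_run_pair`.
#' @export
source_run_pair <- function(npc, pc, reduction_fraction = 0.30) {
  stopifnot(inherits(npc, "concentration_field"),
            inherits(pc, "concentration_field"))
  if (npc$run_kind != "NPC" || pc$run_kind != "PC") {
    abort("`npc` must be an NPC run and `pc` a PC run.",
          class = "pmburden_validation_error")
  }
  for (fld in c("species", "scenario_id", "year")) {
    if (!identical(npc[[fld]], pc[[fld]])) {
      abort(sprintf("NPC and PC runs differ in `%s`.", fld),
            class = "pmburden_validation_error")
    }
  }
  validate_alignment(list(npc, pc))
  if (!is.numeric(reduction_fraction) || length(reduction_fraction) != 1L ||
      !is.finite(reduction_fraction) ||
      reduction_fraction <= 0 || reduction_fraction > 1) {
    abort("`reduction_fraction` must lie in (0, 1].",
          class = "pmburden_domain_error")
  }
  structure(
    list(npc = npc, pc = pc,
         reduction_fraction = as.numeric(reduction_fraction)),
    class = "source_run_pair"
  )
}

#' Gridded population by 5-year age group
#'
#' Per-cell head counts disaggregated into the standard 5-year age groups
#' `"0-4"` through `"85+"`.
#'
#' @param grid A [grid_spec()].
#' @param counts Numeric matrix, `n_cells(grid)` rows by `length(age_groups)`
#'   columns, non-negative.
#' @param age_groups Ordered age-group labels; default [age_group_labels()].
#' @param year Integer calendar year.
#'
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(grid, counts, age_groups = age_group_labels(),
                            year) {
  stopifnot(inherits(grid, "grid_spec"))
  counts <- as.matrix(counts)
  if (nrow(counts) != n_cells(grid) || ncol(counts) != length(age_groups)) {
    abort(sprintf("`counts` must be %d cells x %d age groups.",
                  n_cells(grid), length(age_groups)),
          class = "pmburden_validation_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("Population counts must be finite and non-negative.",
          class = "pmburden_validation_error")
  }
  check_age_groups(age_groups)
  colnames(counts) <- age_groups
  structure(
    list(grid = grid, counts = counts, age_groups = age_groups,
         year = as.integer(year)),
    class = "population_grid"
  )
}

#' @export
format.population_grid <- function(x, ...) {
  sprintf("<population_grid %d: %.4g persons over %d cells x %d age groups>",
          x$year, sum(x$counts), nrow(x$counts), ncol(x$counts))
}

#' @export
print.population_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Standard 5-year age-group labels, 0-4 through 85+
#' @return Character vector of 18 labels.
#' @export
age_group_labels <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

check_age_groups <- function(age_groups) {
  if (!identical(as.character(age_groups), age_group_labels())) {
    abort("`age_groups` must be the contiguous 5-year groups \"0-4\" .. \"85+\".",
          class = "pmburden_validation_error")
  }
  invisible(TRUE)
}

burden_endpoints <- c("all_cause_chronic", "all_cause_acute",
                      "LC", "COPD", "IHD", "stroke", "LRI", "NCD_LRI")

#' Validate a baseline-mortality table
#'
#' A baseline-mortality table is a data frame with columns `endpoint`,
#' `age_group` and `rate` (deaths per person-year, `0 <= rate < 1`), one row
#' per (endpoint, age group).  Rates are treated as exposure-free hazards
#' held fixed across projection years.
#'
#' @param tbl A data frame to validate.
#' @return `tbl` as a tibble, invisibly validated.
#' @export
as_baseline_mortality <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("endpoint", "age_group", "rate")
  if (!all(need %in% names(tbl))) {
    abort("Baseline mortality needs columns endpoint, age_group, rate.",
          class = "pmburden_validation_error")
  }
  if (any(!is.finite(tbl$rate)) || any(tbl$rate < 0) || any(tbl$rate >= 1)) {
    abort("Baseline rates must satisfy 0 <= rate < 1.",
          class = "pmburden_validation_error")
  }
  bad <- !tbl$endpoint %in% burden_endpoints
  if (any(bad)) {
    abort(sprintf("Unknown endpoint(s): %s.",
                  paste(unique(tbl$endpoint[bad]), collapse = ", ")),
          class = "pmburden_validation_error")
  }
  if (anyDuplicated(tbl[c("endpoint", "age_group")])) {
    abort("Duplicate (endpoint, age_group) rows in baseline mortality.",
          class = "pmburden_validation_error")
  }
  tbl
}

#' Check that gridded objects share an identical grid
#'
#' All downstream arithmetic assumes cellwise correspondence; this verifies
#' that every object carries the same [grid_spec()] — dimensions, cell area
#' and region labels alike — and raises an alignment error naming the first
#' differing component otherwise.
#'
#' @param objs List of two or more objects carrying a `$grid` (or grid specs
#'   themselves).
#' @return Invisibly `TRUE` if aligned.
#' @export
#' @examples
#' g <- grid_spec(2, 2)
#' f1 <- concentration_field(g, rep(1, 4), "total_pm25", "CLE", 2010)
#' f2 <- concentration_field(g, rep(2, 4), "soa", "CLE", 2010)
#' validate_alignment(list(f1, f2))
validate_alignment <- function(objs) {
  if (!is.list(objs) || length(objs) < 2L) {
    abort("`validate_alignment()` needs at least two gridded objects.",
          class = "pmburden_validation_error")
  }
  grids <- lapply(objs, function(o) {
    if (inherits(o, "grid_spec")) o else o$grid
  })
  ref <- grids[[1L]]
  for (k in seq_along(grids)[-1L]) {
    g <- grids[[k]]
    if (!inherits(g, "grid_spec")) {
      abort(sprintf("Object %d carries no grid_spec.", k),
            class = "pmburden_alignment_error")
    }
    for (fld in c("n_rows", "n_cols", "cell_area")) {
      if (!identical(ref[[fld]], g[[fld]])) {
        abort(sprintf("Grid mismatch in `%s`: object 1 has %s, object %d has %s.",
                      fld, format(ref[[fld]]), k, format(g[[fld]])),
              class = "pmburden_alignment_error")
      }
    }
    if (!identical(ref$region_labels, g$region_labels)) {
      i <- which(ref$region_labels != g$region_labels)[1L]
      abort(sprintf(
        "Grid mismatch in `region_labels` at cell %d: \"%s\" vs \"%s\" (object %d).",
        i, ref$region_labels[i], g$region_labels[i], k),
        class = "pmburden_alignment_error")
    }
  }
  invisible(TRUE)
}
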