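#' Write a concentration field to a self-describing text raster
#'
#' The on-disk format is a plain-text, self-describing raster: a fixed magic
#' line, tab-separated `key<TAB>value` metadata (species, scenario, year,
#' run kind, perturbed source, dimensions, cell area, region labels), then
#' the cell values row-major, one grid row per line, printed at full double
#' precision (`%.17g`) so that a write/read cycle is bit-identical.
#'
#' @param field A valid [concentration_field()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "concentration_field")) {
    abort("`field` must be a concentration_field.",
          class = "pmburden_validation_error")
  }
  g <- field$grid
  regions <- unique(g$region_labels)
  region_index <- match(g$region_labels, regions)
  header <- c(
    "pmburden-grid\t1",
    paste0("species\t", field$species),
    paste0("scenario_id\t", field$scenario_id),
    paste0("year\t", field$year),
    paste0("run_kind\t", field$run_kind),
    paste0("perturbed_source\t", field$perturbed_source),
    paste0("n_rows\t", g$n_rows),
    paste0("n_cols\t", g$n_cols),
    paste0("cell_area_km2\t", sprintf("%.17g", g$cell_area)),
    paste0("regions\t", paste(regions, collapse = "\t")),
    paste0("region_index\t", paste(region_index, collapse = " ")),
    "values"
  )
  m <- matrix(field$values, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(
                    sprintf("Cannot open `%s` for writing: %s",
                            path, conditionMessage(e)),
                    class = "pmburden_io_error"))
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a concentration field written by [write_field()]
#'
#' @param path File path.
#' @param selector Optional named list of metadata to require
#'   (any of `species`, `scenario_id`, `year`, `run_kind`,
#'   `perturbed_source`); a mismatch raises a format error naming the
#'   selector entry.
#' @return A [concentration_field()].
#' @export
read_field <- function(path, selector = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File `%s` does not exist.", path),
          class = "pmburden_io_error")
  }
  lines <- readLines(path)
  if (length(lines) < 12L || !identical(lines[[1L]], "pmburden-grid\t1")) {
    abort(sprintf("`%s` is not a pmburden grid file.", path),
          class = "pmburden_format_error")
  }
  vstart <- match("values", lines)
  if (is.na(vstart)) {
    abort(sprintf("`%s` has no `values` section.", path),
          class = "pmburden_format_error")
  }
  kv <- strsplit(lines[2:(vstart - 1L)], "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  get1 <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) abort(sprintf("`%s` lacks header key `%s`.", path, key),
                        class = "pmburden_format_error")
    kv[[i]][-1L]
  }
  n_rows <- as.integer(get1("n_rows"))
  n_cols <- as.integer(get1("n_cols"))
  regions <- get1("regions")
  region_index <- as.integer(strsplit(get1("region_index"), " ",
                                      fixed = TRUE)[[1L]])
  grid <- grid_spec(n_rows, n_cols,
                    cell_area = as.numeric(get1("cell_area_km2")),
                    region_labels = regions[region_index])
  value_lines <- lines[(vstart + 1L):length(lines)]
  if (length(value_lines) != n_rows) {
    abort(sprintf("`%s`: expected %d value rows, found %d.",
                  path, n_rows, length(value_lines)),
          class = "pmburden_format_error")
  }
  values <- scan(text = paste(value_lines, collapse = "\n"),
                 what = double(), quiet = TRUE)
  meta <- list(species = get1("species"),
               scenario_id = get1("scenario_id"),
               year = as.integer(get1("year")),
               run_kind = get1("run_kind"),
               perturbed_source = get1("perturbed_source"))
  if (!is.null(selector)) {
    for (key in names(selector)) {
      want <- selector[[key]]
      have <- meta[[key]]
      if (is.null(have)) {
        abort(sprintf("Unknown selector entry `%s`.", key),
              class = "pmburden_format_error")
      }
      if (!identical(as.character(have), as.character(want))) {
        abort(sprintf("`%s` does not match selector %s=%s (file has %s).",
                      path, key, want, have),
              class = "pmburden_format_error")
      }
    }
  }
  concentration_field(grid, values, meta$species, meta$scenario_id,
                      meta$year, meta$run_kind, meta$perturbed_source)
}

#' Read a baseline-mortality CSV
#'
#' Expects columns `endpoint`, `age_group`, `rate` (deaths per person-year).
#'
#' @param path CSV path.
#' @return A validated baseline-mortality tibble.
#' @export
read_baseline_mortality <- function(path) {
  as_baseline_mortality(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a baseline-mortality table as CSV
#' @param tbl A baseline-mortality tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_baseline_mortality <- function(tbl, path) {
  readr::write_csv(as_baseline_mortality(tbl), path)
  invisible(path)
}
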