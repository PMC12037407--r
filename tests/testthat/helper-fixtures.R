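# Small in-code fixtures shared across test files.

tiny_grid <- function(n_rows = 1, n_cols = 1, regions = "domain") {
  grid_spec(n_rows, n_cols, cell_area = 2500, region_labels = regions)
}

tiny_field <- function(values, grid = tiny_grid(1, length(values)),
                       species = "total_pm25", scenario = "CLE",
                       year = 2010, run_kind = "NPC", source = "none") {
  concentration_field(grid, values, species, scenario, year,
                      run_kind, source)
}

# population with every person in one age group
one_group_pop <- function(grid, persons_per_cell, group = "40-44",
                          year = 2010) {
  counts <- matrix(0, n_cells(grid), 18,
                   dimnames = list(NULL, age_group_labels()))
  counts[, group] <- persons_per_cell
  population_grid(grid, counts, year = year)
}

flat_baseline <- function(endpoint = "all_cause_chronic", rate = 0.01) {
  tibble::tibble(endpoint = endpoint, age_group = age_group_labels(),
                 rate = rate)
}

# random valid field for property-style loops
random_field <- function(seed, n_rows = 3, n_cols = 4) {
  set.seed(seed)
  regions <- sample(c("central-eastern", "other"), n_rows * n_cols,
                    replace = TRUE)
  g <- grid_spec(n_rows, n_cols, cell_area = runif(1, 100, 5000),
                 region_labels = regions)
  kind <- sample(c("NPC", "PC"), 1)
  src <- if (kind == "PC") sample(c("re", "bi", "in", "tr"), 1) else "none"
  concentration_field(
    g, runif(n_rows * n_cols, 0, 80),
    species = sample(c("total_pm25", "soa", "sia", "primary_pm25"), 1),
    scenario_id = sample(c("CLE", "MFR", "HIST"), 1),
    year = sample(2010:2049, 1), run_kind = kind, perturbed_source = src)
}

ncd_lri_params <- function() {
  gemm_params("NCD_LRI", theta = 0.1430, alpha = 1.6, mu = 15.5, nu = 36.8)
}
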