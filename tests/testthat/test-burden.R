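# Independent brute-force oracle: explicit double loop over cells and ages.
brute_force_deaths <- function(cvals, counts, rates, rr_fun, af_form) {
  total <- 0
  for (cell in seq_along(cvals)) {
    rr <- rr_fun(cvals[cell])
    af <- if (af_form == "ratio") (rr - 1) / rr else rr - 1
    for (a in seq_along(rates)) {
      total <- total + counts[cell, a] * rates[a] * af
    }
  }
  unname(total)
}

test_that("attributable deaths match brute-force enumeration exactly", {
  g <- tiny_grid(1, 3, regions = c("central-eastern", "other", "other"))
  cvals <- c(42.0, 17.3, 6.9)
  conc <- tiny_field(cvals, g)
  ages <- c("30-34", "60-64", "85+")
  counts <- matrix(0, 3, 18, dimnames = list(NULL, age_group_labels()))
  counts[, ages] <- matrix(c(1e5, 2e5, 3e4,
                             5e4, 1e5, 2e4,
                             8e4, 6e4, 1e4), 3, 3, byrow = TRUE)
  pop <- population_grid(g, counts, year = 2010)
  rates <- c(0.002, 0.008, 0.05)
  base <- tibble::tibble(endpoint = "IHD", age_group = ages, rate = rates)
  p <- gemm_params("IHD", theta = 0.25, alpha = 1.9, mu = 12, nu = 40.2)
  spec <- endpoint_spec("IHD", "gemm", applicable_ages = ages)
  for (form in c("ratio", "delta")) {
    got <- attributable_deaths(conc, pop, base, spec, p, af_form = form)
    want <- brute_force_deaths(cvals, counts[, ages], rates,
                               function(c) gemm_rr(c, p), form)
    expect_equal(got$deaths[got$region == "all"], want, tolerance = 1e-14)
  }
  # linear pathway against the same oracle
  erf <- linear_erf()
  lspec <- endpoint_spec("all_cause_chronic", "linear",
                         applicable_ages = ages)
  lbase <- tibble::tibble(endpoint = "all_cause_chronic",
                          age_group = ages, rate = rates)
  got <- attributable_deaths(conc, pop, lbase, lspec, erf)
  want <- brute_force_deaths(cvals, counts[, ages], rates,
                             function(c) linear_rr(c, erf), "ratio")
  expect_equal(got$deaths[got$region == "all"], want, tolerance = 1e-14)
})

test_that("the one-cell closed-form example yields 800 deaths", {
  g <- tiny_grid(1, 1)
  conc <- tiny_field(10, g)
  pop <- one_group_pop(g, 1e6)
  base <- flat_baseline(rate = 0.01)
  spec <- endpoint_spec("all_cause_chronic", "linear")
  got <- attributable_deaths(conc, pop, base, spec, linear_erf(),
                             af_form = "delta")
  expect_equal(got$deaths[got$region == "all"], 800)
})

test_that("no exposure above the counterfactual means no burden", {
  g <- tiny_grid(2, 2)
  pop <- one_group_pop(g, 1e5)
  zero <- tiny_field(rep(0, 4), g)
  lin <- attributable_deaths(zero, pop, flat_baseline(),
                             endpoint_spec("all_cause_chronic", "linear"),
                             linear_erf())
  expect_true(all(lin$deaths == 0))
  at_cutoff <- tiny_field(rep(2.4, 4), g)
  gm <- attributable_deaths(at_cutoff, pop, flat_baseline("NCD_LRI"),
                            endpoint_spec("NCD_LRI", "gemm"),
                            ncd_lri_params())
  expect_true(all(gm$deaths == 0))
})

test_that("raising any cell's concentration never decreases deaths", {
  g <- tiny_grid(2, 2)
  pop <- one_group_pop(g, 1e5)
  base <- flat_baseline("NCD_LRI")
  spec <- endpoint_spec("NCD_LRI", "gemm")
  p <- ncd_lri_params()
  cvals <- c(5, 15, 30, 60)
  nat <- function(cv) {
    out <- attributable_deaths(tiny_field(cv, g), pop, base, spec, p)
    out$deaths[out$region == "all"]
  }
  ref <- nat(cvals)
  for (i in 1:4) {
    up <- cvals; up[i] <- up[i] + 10
    expect_gte(nat(up), ref)
  }
})

test_that("regional rows decompose the national burden", {
  g <- tiny_grid(2, 3, regions = c("a", "a", "b", "b", "c", "c"))
  pop <- one_group_pop(g, c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5))
  conc <- tiny_field(c(10, 20, 30, 40, 50, 60), g)
  out <- attributable_deaths(conc, pop, flat_baseline(),
                             endpoint_spec("all_cause_chronic", "linear"),
                             linear_erf())
  regions <- out$deaths[out$region != "all"]
  national <- out$deaths[out$region == "all"]
  expect_equal(sum(regions), national, tolerance = 1e-9 * national)
})

test_that("missing baseline rows raise a configuration error naming them", {
  g <- tiny_grid(1, 1)
  pop <- one_group_pop(g, 1e5)
  base <- tibble::tibble(endpoint = "IHD", age_group = "30-34", rate = 0.01)
  expect_error(
    attributable_deaths(tiny_field(10, g), pop, base,
                        endpoint_spec("IHD", "gemm"), ncd_lri_params()),
    class = "pmburden_config_error")
  expect_error(
    attributable_deaths(tiny_field(10, g), pop, base,
                        endpoint_spec("IHD", "gemm"), ncd_lri_params()),
    "IHD")
})

test_that("pathway totals add their components", {
  expect_equal(linear_total_deaths(0.37e6, 3.08e6), 3.45e6)
  expect_equal(linear_total_deaths(0, 5), 5)
  expect_error(linear_total_deaths(-1, 5), class = "pmburden_domain_error")
  causes <- c(LC = 0.17, COPD = 0.29, IHD = 0.47, stroke = 0.15, LRI = 0.07)
  expect_equal(nonlinear_total_deaths(causes), 1.15)
  expect_equal(nonlinear_total_deaths(c(causes * 0)), 0)
  expect_error(nonlinear_total_deaths(causes[-1]),
               class = "pmburden_config_error")
  expect_equal(nonlinear_total_deaths(c(NCD_LRI = 1.3), mode = "ncd_lri"),
               1.3)
})

test_that("joint NCD+LRI burden dominates summed causes on the bundled curves", {
  params <- default_gemm_params()
  five <- c("LC", "COPD", "IHD", "stroke", "LRI")
  # premise: the joint curve's RR dominates each cause's over the range used
  cs <- seq(3, 120, by = 1)
  for (ep in five) {
    expect_true(all(gemm_rr(cs, params$NCD_LRI) >= gemm_rr(cs, params[[ep]])))
  }
  cfg <- synthetic_config(seed = 6, n_rows = 6, n_cols = 6)
  suite <- generate_concentration_suite(cfg)
  conc <- Filter(function(f) f$scenario_id == "CLE" && f$year == 2010 &&
                   f$run_kind == "NPC" && f$species == "total_pm25",
                 suite$fields)[[1]]
  pop <- generate_population(cfg)[["2010"]]
  base <- generate_baseline_mortality(cfg)
  deaths <- vapply(c(five, "NCD_LRI"), function(ep) {
    out <- attributable_deaths(conc, pop, base, endpoint_spec(ep, "gemm"),
                               params[[ep]])
    out$deaths[out$region == "all"]
  }, numeric(1))
  expect_gte(deaths[["NCD_LRI"]],
             nonlinear_total_deaths(deaths[five], "sum_causes"))
})

test_that("source burdens are symmetric and additive under the delta form", {
  cfg <- synthetic_config(seed = 12, n_rows = 6, n_cols = 6)
  pop <- generate_population(cfg)[["2010"]]
  base <- generate_baseline_mortality(cfg)
  f <- rep(8, 36)
  two_same <- source_attributable_deaths(list(re = f, tr = f), pop, base,
                                         scenario_id = "CLE", year = 2010)
  re <- two_same$deaths[two_same$source == "re" & two_same$region == "all" &
                          two_same$endpoint == "linear_total"]
  tr <- two_same$deaths[two_same$source == "tr" & two_same$region == "all" &
                          two_same$endpoint == "linear_total"]
  expect_equal(re, tr)

  suite <- generate_concentration_suite(cfg)
  rec <- apportion_suite(Filter(function(x) x$scenario_id == "CLE" &&
                                  x$year == 2010, suite$fields))
  per_src <- source_attributable_deaths(rec, pop, base, af_form = "delta")
  sum_of_parts <- sum(per_src$deaths[per_src$endpoint == "linear_total" &
                                       per_src$region == "all"])
  combined_field <- Reduce(`+`, rec[c("re", "bi", "in", "tr")])
  combined <- source_attributable_deaths(list(bi = combined_field), pop,
                                         base, af_form = "delta")
  expect_equal(sum_of_parts,
               combined$deaths[combined$endpoint == "linear_total" &
                                 combined$region == "all"],
               tolerance = 1e-12)
})

test_that("root-finding on national deaths recovers the linear relative risk", {
  cfg <- synthetic_config(seed = 21, n_rows = 8, n_cols = 8)
  suite <- generate_concentration_suite(cfg)
  conc <- Filter(function(f) f$scenario_id == "CLE" && f$year == 2010 &&
                   f$run_kind == "NPC" && f$species == "total_pm25",
                 suite$fields)[[1]]
  pop <- generate_population(cfg)[["2010"]]
  base <- generate_baseline_mortality(cfg)
  spec <- endpoint_spec("all_cause_chronic", "linear")
  national <- function(rr10) {
    out <- attributable_deaths(conc, pop, base, spec, linear_erf(rr10))
    out$deaths[out$region == "all"]
  }
  target <- national(1.08)
  root <- uniroot(function(r) national(r) - target, c(1.0001, 1.5),
                  tol = 1e-10)
  expect_lt(abs(root$root - 1.08), 1e-6)
})
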