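fixture <- read_table1_fixture()
lin_cle <- fixture_scenario_series(fixture, "linear", "CLE")
lin_mfr <- fixture_scenario_series(fixture, "linear", "MFR")
nonlin_cle <- fixture_scenario_series(fixture, "nonlinear", "CLE")
nonlin_mfr <- fixture_scenario_series(fixture, "nonlinear", "MFR")

test_that("reporting rounds half away from zero only at the boundary", {
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-8.5), -9)
  expect_equal(round_half_away(2.3875, 2), 2.39)
  expect_equal(round_half_away(-13.4), -13)
  expect_equal(round_half_away(0.445, 2), 0.45)
})

test_that("percent changes versus the baseline match the fixture", {
  expect_equal(percent_change_vs_baseline(lin_cle, "total", 2049), -43)
  expect_equal(percent_change_vs_baseline(lin_mfr, "total", 2049), -80)
  expect_equal(percent_change_vs_baseline(lin_cle, "CD", 2049), -42)
  expect_equal(percent_change_vs_baseline(lin_mfr, "CD", 2049), -80)
  # identity year gives zero change
  expect_equal(percent_change_vs_baseline(lin_cle, "total", 2010), 0)
})

test_that("multi-year averages weight the simulated years equally", {
  expect_equal(annual_average(lin_cle, "total"), 2.39)
  expect_equal(annual_average(nonlin_cle, "total"), 2.07)
  expect_equal(annual_average(lin_mfr, "total"), 1.46)
  expect_equal(annual_average(nonlin_mfr, "total"), 1.33)
  const <- scenario_series("X", tibble::tibble(
    year = c(2010, 2020, 2030, 2040, 2049), endpoint = "total", value = 1.7))
  expect_equal(annual_average(const, "total"), 1.7)
  expect_error(annual_average(lin_cle, "total", years = c(2020, 2035)),
               class = "pmburden_range_error")
})

test_that("nonlinear-versus-linear deltas match the fixture", {
  expect_equal(linear_vs_nonlinear_delta(lin_cle, nonlin_cle), -13)
  expect_equal(linear_vs_nonlinear_delta(lin_mfr, nonlin_mfr), -9)
  expect_equal(linear_vs_nonlinear_delta(lin_cle, lin_cle), 0)
})

test_that("cause shares reproduce the fixture's 2010 column", {
  five <- c("LC", "COPD", "IHD", "stroke", "LRI")
  vals_2010 <- setNames(
    vapply(five, function(ep)
      fixture$deaths_million[fixture$model == "nonlinear" &
                               fixture$endpoint == ep &
                               fixture$year == 2010], numeric(1)), five)
  expect_equal(cause_share(vals_2010, "IHD", five), 41)
  expect_equal(cause_share(vals_2010, "IHD", "IHD"), 100)
  lin_2010 <- c(AD = 0.37, CD = 3.08, total = 3.45)
  expect_equal(cause_share(lin_2010, "CD", "total"), 89)
  expect_error(cause_share(c(a = 1, b = 0), "a", "b"),
               class = "pmburden_domain_error")
})

test_that("scenario differences give the absolute avoided deaths", {
  expect_equal(scenario_difference(lin_cle, "total", 2010, 2049), 1.47)
  expect_equal(scenario_difference(lin_mfr, "total", 2010, 2049), 2.76)
  expect_equal(scenario_difference(lin_cle, "total", 2030, 2030), 0)
  expect_error(scenario_difference(lin_cle, "total", 2010, 2035),
               class = "pmburden_range_error")
})

test_that("linear totals in the fixture equal acute plus chronic", {
  for (scen in list(c("HIST", 2010), c("CLE", 2049), c("MFR", 2049))) {
    pick <- function(ep) fixture$deaths_million[
      fixture$model == "linear" & fixture$endpoint == ep &
        fixture$scenario == scen[1] & fixture$year == as.integer(scen[2])]
    expect_equal(linear_total_deaths(pick("AD"), pick("CD")), pick("total"))
  }
})

test_that("source-reduction decomposition sums to one and flags degeneracy", {
  equal_delta <- source_reduction_decomposition(
    c(re = 10, bi = 10, `in` = 10, tr = 10),
    c(re = 5, bi = 5, `in` = 5, tr = 5))
  expect_equal(equal_delta$share, rep(0.25, 4))
  one_flat <- source_reduction_decomposition(
    c(re = 10, bi = 20, `in` = 10, tr = 10),
    c(re = 10, bi = 5, `in` = 5, tr = 5))
  expect_equal(one_flat$share[one_flat$source == "re"], 0)
  expect_equal(sum(one_flat$share), 1)
  expect_error(source_reduction_decomposition(c(re = 1, bi = 1),
                                              c(re = 2, bi = 3)),
               class = "pmburden_domain_error")
})

test_that("reporting functions are pure: reruns give identical output", {
  a <- c(percent_change_vs_baseline(lin_cle, "total", 2049),
         annual_average(nonlin_mfr, "total"),
         linear_vs_nonlinear_delta(lin_cle, nonlin_cle))
  b <- c(percent_change_vs_baseline(lin_cle, "total", 2049),
         annual_average(nonlin_mfr, "total"),
         linear_vs_nonlinear_delta(lin_cle, nonlin_cle))
  expect_identical(a, b)
})

test_that("a biomass-dominated decline is attributed mostly to biomass", {
  # synthetic pipeline where bi carries the largest share of the decline
  cfg <- synthetic_config(seed = 31, n_rows = 8, n_cols = 8)
  suite <- generate_concentration_suite(cfg)
  pops <- generate_population(cfg)
  base <- generate_baseline_mortality(cfg)
  burden_for <- function(yr) {
    fields <- Filter(function(f) f$scenario_id == "MFR" && f$year == yr,
                     suite$fields)
    rec <- apportion_suite(fields, cfg$reduction_fraction)
    source_attributable_deaths(rec, pops[[as.character(yr)]], base,
                               scenario_id = "MFR", year = yr)
  }
  dec <- source_reduction_decomposition(burden_for(2010), burden_for(2049))
  bi_share <- dec$share[dec$source == "bi"]
  expect_true(all(bi_share > dec$share[dec$source != "bi"]))
})
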