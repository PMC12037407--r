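---
title: "Source-apportioned PM2.5 health burdens: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-apportioned PM2.5 health burdens: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmburden)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, what
the synthetic generator does and does not emulate, and the design choices
made where more than one defensible option existed.

## The problem

Ambient fine particulate matter (PM2.5) is a leading environmental risk
factor for premature death. Policy analysis needs three things joined up:
(i) *attribution* — how much of the ambient concentration is due to each
controllable emission source; (ii) *exposure-response* — how mortality risk
rises with concentration; and (iii) *projection* — how the burden evolves
under emission scenarios as both air quality and the population's age
structure change. `pmburden` implements that chain for gridded annual-mean
concentration fields, with a synthetic-data module that stands in for the
chemistry-transport and demographic inputs so the whole pipeline is
testable end to end.

## Perturbation-based source apportionment

Chemistry-transport models cannot tag every secondary particle by its
emitting sector, so attribution uses sensitivity runs: alongside the
unperturbed reference (NPC) run, one run per source (PC) in which that
source's emissions are reduced by a fraction `f`. The source's
concentration contribution per cell is the scaled difference

$$C_P = \frac{C_{NPC} - C_{PC}}{f}.$$

The default `f = 0.30` balances two failure modes: a tiny perturbation
drowns in numerical noise far from the source, while a total shutdown
leaves the near-linear regime of the aerosol chemistry and the scaling
becomes biased. `f` is a parameter rather than a constant precisely so
this trade-off can be probed.

Nonlinear chemistry (or mismatched run pairs) can make $C_{PC} > C_{NPC}$
in individual cells. Those cells are *retained* with negative
contributions — clipping them would silently bias national sums — and a
warning fires when their fraction exceeds a threshold (default 5%). A
`floor_zero` flag provides the clipped behaviour for users who want
non-negative maps; it is off by default.

Two bookkeeping identities complete the stage: a source's primary PM2.5 is
its total contribution minus its secondary inorganic (SIA: sulfate,
nitrate and ammonium particle families at full particle weight) and
secondary organic (SOA) parts, and the domain's secondary burden is the
NPC run's SOA plus SIA.

## Exposure-response functions

**Linear pathway.** Risk rises in a straight line:
$RR(c) = 1 + (RR_{10} - 1)\,(c - c_0)_+/10$. The chronic default
$RR_{10} = 1.08$ per 10 µg m⁻³ is the WHO-recommended all-cause long-term
relative risk. The counterfactual $c_0$ defaults to 0: the linear pathway
traditionally attributes risk from the first microgram, and no threshold
is asserted for it here — a declared choice, since the convention is not
universal.

The *acute* (short-term) coefficient is deliberately a configuration
value, not a bundled constant. Its placeholder default (1.0096 per
10 µg m⁻³) was fixed once so that acute deaths make up roughly 11% of the
combined linear total — the structural split seen in large national
assessments — and is documented as such; substantive work should supply a
short-term coefficient from the epidemiological literature.

**Nonlinear pathway (GEMM).** The Global Exposure Mortality Model
hazard-ratio family, with $z = (c - 2.4)_+$ µg m⁻³:

$$RR(c) = \exp\!\left\{\theta\,
  \frac{\ln(z/\alpha + 1)}{1 + \exp(-(z - \mu)/\nu)}\right\}.$$

$\theta$ scales the overall strength; $\alpha$ sets the curvature of the
logarithmic rise (small $\alpha$ means steep low-concentration response);
$\mu$ and $\nu$ place and widen the logistic transition that flattens the
curve at high concentrations. The 2.4 µg m⁻³ counterfactual is the lowest
exposure observed in the underlying cohorts; below it $RR = 1$ exactly.
The function is continuous and non-decreasing in $c$ for $\theta \ge 0$ —
both properties are enforced by tests across random parameter draws.

The per-cause parameter values are *data, not code*: they ship in an
editable CSV (`gemm_params_synthetic.csv`) whose values are a plausible
synthetic set, because the authoritative published fit could not be
transcribed here with confidence. Every test pins its expectations to
declared fixture values, so package correctness never depends on that
file's contents — the one deliberate exception being the joint NCD+LRI
row, whose values (θ = 0.1430, α = 1.6, μ = 15.5, ν = 36.8) are the
declared reference fixture used throughout the tests.

**Attributable fraction.** Both pathways convert risk to burden through
$AF = (RR-1)/RR$ by default. The strictly proportional alternative
$AF = RR - 1$ is available as `af_form = "delta"`: the published burden
formula behind the scenario tables is not printed anywhere, both forms are
standard, and the switch makes the ambiguity testable rather than hidden.
Under the delta form the linear pathway is exactly additive across
sources, which is why source burdens default to it.

## Burden accounting

Attributable deaths multiply, per cell and 5-year age group, population ×
baseline mortality rate × AF, then aggregate by region label and
nationally. Choices worth stating:

* **GEMM endpoints apply to ages 25+** by default (the hazard-ratio
  framework is adult-cohort based); the linear all-cause pathway applies
  to all ages. Both are configurable per endpoint.
* **Baseline mortality is year-invariant**, mirroring the common practice
  of holding one reference year's rates fixed across projections; what
  changes over time is the population size, its age structure, and the
  concentrations.
* **Two nonlinear totalization modes** exist: summing the five cause
  burdens (lung cancer, COPD, ischemic heart disease, stroke, lower
  respiratory infections) or evaluating the single joint NCD+LRI curve.
  Published tables are ambiguous about which produced their totals — the
  joint-curve total can legitimately exceed the cause sum — so both are
  implemented and neither is privileged.
* **Source burdens use the linear pathway only** by default. A nonlinear
  function evaluated on a concentration *fraction* has no clean
  attributable-burden interpretation, and linear source attribution is
  the published convention.

## Demography

Age shares are supplied at anchor years and linearly interpolated
componentwise in between, then renormalized to sum to one (interpolation
preserves the simplex only up to rounding; renormalization makes it
exact). Shares — not absolute counts — are interpolated: the underlying
sources publish structure and totals separately, and share interpolation
keeps the two independent. No extrapolation outside the anchors is
permitted. The default structure ages the 65+ share from exactly 8% (2010)
to exactly 23% (2049), with plausible pyramid shapes within each block.

## The synthetic world

The generator emulates the statistical features the burden math actually
depends on, and nothing else:

* a deterministic high-pollution block ("central-eastern" region label)
  covering ~25% of cells at 4× the background weight, times smoothed
  log-normal noise for spatial correlation — no geostatistical fitting,
  because only the exposure-population covariance matters downstream;
* national-mean totals declining *exactly* linearly from a 2010 mean of
  19.7 µg m⁻³ by 34% (CLE-like) or 78% (MFR-like) to 2049, above a 3
  µg m⁻³ non-anthropogenic background;
* four additive source contributions with shares bi 0.40, in 0.34,
  re 0.16, tr 0.10 of the anthropogenic mass; perturbed runs are
  synthesized *at the concentration level* (chemistry-transport is out of
  scope), so that at `nonlinearity_eps = 0` the apportionment identity
  holds to machine precision, and at `eps > 0` the response is damped in
  proportion to the local source concentration — recovery error then grows
  monotonically with `eps`, which the tests verify at 0, 0.05 and 0.1;
* one shared population series for both scenarios (so scenario contrasts
  isolate concentrations), totalling 1.34 billion in 2010, peaking at 1.45
  billion in 2020 and declining 11% below 2010 by 2049, with 75% of people
  in the hotspot block and the ageing structure above;
* deterministic Gompertz-like baseline mortality (all-cause hazard
  $2\times10^{-4} e^{0.085\,\mathrm{age}}$) with cause rates as fixed
  fractions of all-cause and NCD+LRI as their sum.

**What passing tests do and do not show.** The synthetic world validates
the *machinery*: exact apportionment recovery, conservation laws,
monotonicity, additivity, share propagation. It does not validate
epidemiological realism — real concentration fields are not separable
into a fixed spatial pattern times a national scalar, real baseline rates
are not a single Gompertz curve, and real source shares vary in space.
One instructive interaction: under the synthetic defaults the CLE-like
linear burden *rises* from 2010 to 2049, because the ageing pyramid
roughly doubles the crude mortality rate while concentrations fall only
34% — whereas assessments using observed cause- and age-specific rates
report declining linear burdens under comparable scenarios. The synthetic
world is a consistency instrument, not a forecast.

## Reporting conventions

Scenario statistics are pure functions of their input tables. Internal
values keep full precision; rounding happens only at the reporting
boundary, *half away from zero* (2.3875 million → 2.39; −13.4% → −13),
the convention that reproduces every checkable printed value in the
bundled fixture. Multi-year averages weight the simulated years
(2020, 2030, 2040, 2049) equally — equal weighting reproduces the
fixture's printed averages exactly, so it is adopted over interpolating
the intervening years. Percent changes are signed internally (reductions
negative) and rendered as positive "reductions" in prose. A known
artefact of fixture-driven reporting: statistics recomputed from values
that were themselves rounded to two decimals can differ by one point from
a source that computed before rounding (e.g. an acute-deaths reduction of
51% vs a printed 52%); the package computes honestly from its inputs and
does not special-case such cells.

Regional aggregation uses the per-cell region labels; the `"all"` label is
reserved for the national-total row, and regional rows always sum to it
(enforced by tests to 1e-9 relative).

## Numerical and degenerate-input choices

* Grid files are a self-describing plain-text raster written at `%.17g`,
  so write→read round-trips are bit-identical; alignment (dimensions,
  cell area *and* region labels) is verified before any cellwise
  arithmetic, with the first differing component named in the error.
* `reduction_fraction ≤ 0` is a domain error; `rr < 1` is a domain error
  for attributable fractions; zero populations and zero denominators
  raise domain errors rather than returning NaN.
* A one-cell (or all-hotspot) grid skips the hotspot population rescaling
  rather than dividing by zero.
* Source-reduction decomposition requires a positive net reduction; a
  non-positive one is a domain error, not a silently negative share.

## Problem sizes

The test suite exercises grids from 1×1 up to the generator's default
50×50 (2,500 cells, 80 fields per suite), with property loops of 50–1,000
random parameter draws; these sizes characterise the pipeline fully while
keeping the suite fast. The acceptance script runs the full default-sized
synthetic pipeline.

## Known limitations

* No map projections or geodesy: the grid is an abstract raster, and the
  regional mask is whatever labelling the data carry.
* No uncertainty propagation: GEMM θ standard errors and confidence
  intervals are out of scope, as are integrated-exposure-response (IER)
  alternatives.
* Morbidity, years-of-life-lost and economic valuation are not computed.
* The bundled GEMM parameter file is synthetic; results on it are
  structurally meaningful but not citable burden estimates.
* Only PM2.5 is handled; ozone and other gaseous burdens are out of scope.
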