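---
title: "Methods: ET0 models, hydrological-year selection and Bayesian-style calibration"
author: "et0calib maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ET0 models, hydrological-year selection and Bayesian-style calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(et0calib)
```

# The problem

Reference crop evapotranspiration (ET₀) — the evapotranspiration of a
hypothetical well-watered grass surface — is the basis of crop
water-requirement and irrigation calculations. The FAO-56 Penman–Monteith
(PM) combination equation is the accepted standard but needs humidity, wind
and radiation data that many stations lack. This package implements a
complete workflow for asking, on one station's record: *which reduced-input
ET₀ model best tracks PM here, and how much does recalibrating its empirical
coefficients against PM help?*

The workflow has four stages: (1) daily ET₀ by five models; (2) selection of
typical hydrological years so the comparison covers wet through dry
conditions; (3) recalibration of the FAO-24 Radiation (FR) coefficients
against PM by an iterative posterior-mean blend; (4) evaluation at daily,
dekad and monthly scales with R², RMSE, MAE and an index of agreement.

# The meteorological chain and its assumptions

The models consume intermediate quantities computed by the standard FAO-56
daily chain, which we adopt wholesale because the PM formulation is defined
in that context:

* Tetens saturation vapour pressure; daily es is the average of es(Tmax) and
  es(Tmin) (using Tmean would underestimate es by Jensen's inequality).
* Actual vapour pressure ea prefers the measured mean vapour pressure when a
  station reports one, else RH/100 · es_day, clamped to saturation. Both
  routes are exposed because records differ in which variable they carry.
* γ = 0.665·10⁻³·P with P measured or from the standard atmosphere at the
  station elevation.
* Solar geometry (inverse relative distance, declination, sunset hour angle)
  gives Ra and the day length N; the hour angle is clamped beyond the polar
  circles.
* Ångström–Prescott Rs = (0.25 + 0.50·n/N)·Ra. The coefficients are the
  FAO-56 defaults: no locally calibrated pair is available, and the model
  comparison is insensitive to a common Rs scaling in its ranking.
* Net radiation with fixed grass albedo 0.23 and a Stefan–Boltzmann net
  longwave with humidity and cloudiness corrections; the relative shortwave
  ratio Rs/Rso is clamped to [0.3, 1] (also the polar-night guard).
* Soil heat flux G = 0 at daily scale; dekad and monthly ET₀ are sums of
  daily values, so no aggregate G correction is applied anywhere.
* Wind is converted to 2 m by the log profile; the anemometer height
  defaults to the 10 m synoptic standard because station metadata rarely
  state it.

**Units.** Radiation enters the simplified models in mm day⁻¹ of
evaporation equivalent (0.408 mm per MJ m⁻², λ = 2.45 MJ kg⁻¹). The
textbook forms of the Priestley–Taylor, Hargreaves and FAO-24 Radiation
equations are dimensionally inconsistent if radiation stays in MJ m⁻²
day⁻¹, so the conversion is applied by default; `et0_params(radiation_in_mm
= FALSE)` computes the literal printed forms for comparison. Negative daily
ET₀ (possible for PM/PT/FR on radiative-deficit winter days) is clamped to
zero.

**Coefficients** (all overridable in `et0_params()`): α = 1.26 (PT),
C₀ = 0.0023 (HA), K = 0.254 mm day⁻¹ and W = 1.07 (MC), (a, b) =
(0.18, 0.50) (FR). The FR intercept is implemented as printed in mm day⁻¹
even though FAO-24's original form uses −0.3; calibration may legitimately
drive it negative, so only the multiplicative coefficients are constrained
positive.

# Typical hydrological years

Annual rainfall is ranked descending and each year given the Weibull
plotting position p = m/(N+1), read as an exceedance frequency (p = 25% is
the wet, high-flow design level; this matches the convention in which the
high-flow year has the largest rainfall). A Pearson Type III distribution is
fitted by moments — sample mean, cv = sd/mean, bias-corrected skew — rather
than probability-plot curve fitting, because the moments fit is closed-form,
reproducible and standard in hydrological practice. The design value at
exceedance p is the quantile of the shifted gamma with shape 4/cs², scale
mean·cv·|cs|/2 and location mean(1 − 2cv/|cs|) (mirrored for negative skew;
normal limit below |cs| = 10⁻⁴, with the skew floored at 10⁻⁶ to avoid the
degenerate shape). For each of p ∈ {0.25, 0.50, 0.75, 0.90} the observed
year whose total is nearest the design value is selected, ties broken
toward the earlier year. Nearest-rainfall matching is asserted as the
selection rule because it operationalises "representative year"; nearest
empirical frequency would be an equally defensible choice and differs only
when two years' totals straddle a design value.

# The calibration scheme and its numerical behaviour

The FR model is affine in its radiation driver d = Δ/(Δ+γ)·0.408·Rs. Taking
daily PM ET₀ as truth, each day yields one estimate of each coefficient:
bᵢ = (ET₀ᵢ − a)/dᵢ and aᵢ = ET₀ᵢ − b·dᵢ. One iteration updates b first —
sample mean Θ̂ and n−1 variance δ̂² of the bᵢ, blended with the prior
α₀ = 0.50 by E = (α₀·δ̂² + Θ̂·w)/(δ̂² + w) — then a with the updated b and
prior 0.18. Iteration stops when both coefficients move less than `tol`
(10⁻⁶) or at `max_iter` (100, flagged not raised). Θ̂ and δ̂² are recomputed
from all included days each iteration (batch recomputation) rather than
sequentially day-by-day, which makes the result order-independent.

Numerical choices and caveats a user should know:

* **Driver filter.** Days with d < `min_driver` (0.05 mm day⁻¹) are
  excluded, not imputed: the b-inversion divides by d and deep-winter or
  polar days would dominate the sample variance. Excluded counts are
  reported.
* **The blend's limits.** w → 0 keeps the priors; w → ∞ trusts the sample
  means. The default w = 0.812 is taken as printed in the scheme this
  implements; no derivation is given there, so it is exposed as
  `prior_weight` with the sample-variance units the formula implies.
* **The fixed point is not the truth.** Even on noise-free data generated
  by FR(a*, b*), the scheme does not return (a*, b*) unless the priors
  already equal the truth: while a ≠ a*, the bᵢ spread as
  b* − (a − a*)/dᵢ, so δ̂² > 0 and shrinkage persists. Worse, the pure
  alternating-means limit amplifies the intercept error by
  mean(d)·mean(1/d) ≥ 1 (AM–HM inequality) per cycle, so the
  data-trusting limit is unstable; the prior anchoring is what stabilises
  the iteration. The tests therefore pin the implementation against an
  independent straight-line re-implementation and against the scheme's true
  invariants (every blend lies between prior and sample mean; truth-priors
  are a fixed point; calibrated RMSE against the standard does not exceed
  the default's), not against exact recovery.
* **R² invariance.** Recalibrating (a, b) is an affine map of the daily
  series, so daily R² against PM is exactly unchanged. At dekad/monthly
  scale the aggregate map is only approximately affine (periods have 8–11
  or 28–31 days), so aggregate R² matches to about 10⁻² rather than
  exactly.

# Evaluation

Dekads are days 1–10, 11–20 and 21–month-end; monthly and dekad ET₀ are
sums of daily values, and a period missing any day is flagged `NA` rather
than summed short. R² is the squared Pearson correlation of the aligned
pairs (not a regression R²); RMSE and MAE are in mm per period; the index
of agreement is implemented, as published, with the denominator centred on
the *simulated* mean (`wi_convention = "paper"`), with the conventional
observed-mean Willmott form available as a switch. Correlation-test
p-values are reported alongside but never drive any selection.

Improvement summaries report both aggregation conventions — the mean of
per-row percent changes, and the percent change of the row means — because
published headline numbers mix them (error metrics per-row, index of
agreement ratio-of-means); each test pins its number to its convention.

# The synthetic world

`generate_station_weather()` emulates the target climate — a temperate
semi-humid/semiarid continental monsoon station — with defaults chosen
once: latitude 38.85°, elevation 17 m (a Haihe-Plain-like city), annual
mean temperature 13 °C with 14.5 °C half-amplitude peaking mid-July, mean
diurnal range 10 °C, mean RH 60% with a late-summer peak, gamma wind with
mean 2.2 m s⁻¹, mean relative sunshine 0.55, and 500 mm expected annual
rainfall with 70% concentrated in a Gaussian summer bump. Temperature noise
is AR(1) with φ = 0.7 and σ = 2 °C so that dekad/monthly aggregation is
non-degenerate. The daily rainfall expectation is constructed so the annual
expectation equals `annual_precip_mean` exactly (occurrence probability
0.35, exponential amounts). One RNG stream is seeded per series and the
caller's RNG state is restored.

What the generator does *not* emulate: multi-day synoptic rain spells,
temperature–sunshine–humidity cross-correlations, drizzle/extreme-value
rain structure, inter-station spatial correlation, or climate trends. A
green test on this world therefore establishes formula correctness,
pipeline plumbing and the direction of the calibration effect — not that
any specific published station-level value is reproduced, which would
require the undeposited raw records.

# Known limitations

* The calibration is a heuristic conjugate-style blend, not a full
  posterior; no uncertainty intervals are produced.
* The standard is modelled PM, not lysimeter measurements; "improvement"
  means closer agreement with PM.
* Pearson III fitting is moments-based; L-moments would be more robust for
  short, skewed records.
* Sub-daily data, measured solar radiation and crop-coefficient ETc are out
  of scope.
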