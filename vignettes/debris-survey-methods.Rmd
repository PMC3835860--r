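---
title: "Methods: quantifying spatial heterogeneity of floating marine debris"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spatial heterogeneity of floating marine debris}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftgrid)
```

`driftgrid` implements the statistical workflow of a ship-based survey of
floating plastic: surface net tows for microplastic, shipboard visual
transects for macrodebris, and the inference layers that turn both into
defensible statements about abundance, spatial structure, detectability and
monitoring power. This vignette is the package's account of those methods —
the models, their assumptions, the tunable parameters, and the design
choices made where the methodology was genuinely open.

## Concentrations and mass arithmetic

A manta net samples the two-dimensional air–sea interface, so
concentrations are preferentially areal. The flowmeter gives a filtered
volume `V` (m³); with the 0.2 m mouth depth the surface area swept is
`V / 0.2` and `areal_concentration()` returns `n / (V / 0.2)` particles
m⁻². The volumetric companion is `n / V`, so `C_m² = 0.2 · C_m³` holds
exactly and is asserted in the tests.

Zooplankton dry biomass from preserved samples loses mass to fixation;
`zoop_corrected_mass()` applies a 20% correction as *measured × 1.20*. The
correction is sometimes stated ambiguously in the literature (add 20% of
the measured mass vs divide by 0.8); the multiplicative-1.20 reading is the
literal interpretation of "a 20% correction factor was applied" and is the
one implemented.

`removal_equivalents()` converts a plastic:plankton dry-mass ratio into the
zooplankton removed per gram of plastic extracted from the neuston:
`1000 / ratio` mg g⁻¹, with carbon at a 0.40 fraction of dry mass. At the
gyre median ratio 1.368 this gives 731 mg zooplankton and 292.4 mg carbon
per gram of plastic. Note that 292.4 is what 731 × 0.40 actually equals;
reports of "approximately 330 mg of carbon" at the same ratio and fraction
are internally inconsistent, and the package reports the arithmetic truth.

Summaries of skewed concentration samples (`summarize_values()`) use order
statistics: median, 5th/95th percentiles with linear interpolation
(quantile type 7 — the convention is rarely stated in survey reports, and
type 7 is R's default and the least surprising), CV in percent, and a
percentile bootstrap (B = 1000, seeded) of the median. Resampling is of
tows, the independent sampling unit, not particles.

## Spatial structure: semivariograms

For station values `z` at geographic coordinates, `pairwise_distances()`
returns haversine great-circle distances on a 6371 km sphere. Planar
"Euclidean" distance on raw degrees would distort longitude spacing by
cos(latitude) ≈ 0.8 at 35°N; great-circle distance is the defensible
choice at 10–1000 km scales and (0°,0°)–(0°,1°) = 111.19 km anchors the
convention in the tests.

`empirical_semivariogram()` offers the classical estimator and the robust
Cressie–Hawkins estimator based on `|z_i − z_j|^{1/2}`, whose fourth-power
mean is bias-corrected by the denominator `2(0.457 + 0.494/|N(h)|)`.
Concentration data are strongly skewed, and a single extreme tow can
dominate squared differences; the tests assert that an injected outlier
perturbs the robust estimate less than the classical one, while on
well-behaved Gaussian fields the two agree within 15%.

Default binning is 15 equal-width bins out to half the maximum pairwise
distance — a standard geostatistical rule of thumb that keeps the long-lag
bins populated. Bins with no pairs are dropped rather than reported as
zero.

`fit_variogram()` fits by weighted least squares with the per-bin pair
counts as weights. The linear family allows a negative slope (observed in
practice for debris, where short-range patchiness can exceed long-range
variance). The Gaussian family is
`γ(h) = τ² + σ²(1 − exp(−(h/φ)²))`; under this parameterization the
practical range (95% of the sill) is `φ√3`, and both are reported to avoid
the parameterization drift between geostatistics packages and textbooks.
The Gaussian fit multi-starts `φ` from five quantiles of the bin centres
(local minima are common in WLS variogram fitting) and bounds all
parameters non-negative; convergence failure from every start raises an
error rather than returning a silent local minimum.

On simulated Gaussian-process tracks (400 points, 1 km spacing, range
10 km) the fitted range lands within a factor of 2 of truth in ≈19 of 20
seeds. Single-realization variogram range estimates are heavy-tailed —
occasionally a realization drifts enough that the empirical variogram
keeps rising and the fitted range runs away — so the acceptance test
asserts the median and an 18-of-20 fraction rather than every seed.

## Distance sampling with binned perpendicular distances

Visual surveys record each detected item in one of seven pre-set
perpendicular-distance bins (0–10, 10–50, 50–100, 100–200, 200–300,
300–600, >600 m), three size classes (small 2–10 cm, medium 10–30 cm,
large >30 cm) and three color classes (white, high-visibility,
low-visibility). `fit_detection()` maximizes the multinomial likelihood of
the closed-bin counts with cell probabilities
`p_j ∝ ∫_bin g(x) dx / ∫_0^W g(x) dx`, assuming items uniform in
perpendicular distance to the truncation `W = 600` m.

Design choices:

- **Truncation.** The open ">600 m" bin is excluded (`W = 600` m): an
  unbounded bin has no finite integral for a uniform `g`, and detection at
  the horizon is not credibly half-normal. Observers count to the horizon;
  the model does not follow them there.
- **Families.** Uniform (0 parameters), half-normal `exp(−x²/2σ²)` (1),
  hazard-rate `1 − exp(−(x/s)^{−b})` (2) — the standard key functions,
  without adjustment series. Six bins cannot identify more than two or
  three parameters, and these three cover flat, shoulder-less and
  shouldered detection shapes. Selection is by AIC = 2k − 2·loglik.
- **Optimization.** The half-normal has one parameter, so a bounded 1-D
  golden-section search on log σ is used (deterministic, no restarts
  needed). The hazard-rate uses L-BFGS-B on log parameters from a fixed
  12-point restart grid; fixed rather than random restarts keep fits fully
  reproducible. Half-normal bin integrals use the closed normal-CDF form;
  hazard-rate integrals use adaptive quadrature.
- **Degenerate data.** All counts in one bin yields a `flagged` fit rather
  than an error; groups with fewer than 10 sightings are not fitted (the
  pipeline skips them; pooling into the size class is the recommended
  manual fallback).

`esw()` integrates the fitted `g` to `W` at relative tolerance 1e-8; for
the half-normal it matches `σ√(π/2)·erf(W/(σ√2))` to 1e-6 in the tests.
`densities()` standardizes all groups to the widest strip:
`CF_g = ESW_max / ESW_g`, corrected sightings `n_g · CF_g`, density
`corrected / (L · ESW_max)` one-sided — algebraically `n_g / (L · ESW_g)`,
and exactly `n / (L · W)` under uniform detection. Correction factors are
computed jointly over all fitted groups (size × color): the widest-strip
group is the natural standard regardless of which classification axis
produced it.

`bootstrap_density_ci()` resamples transect segments (the independent
survey unit) with replacement, refits, and takes percentile intervals. In
a 200-survey simulation (100 segments of 2 km, density 40 km⁻²,
half-normal σ = 150 m, B = 199) coverage is 93–94% — the familiar mild
undercoverage of percentile intervals at moderate segment counts, inside
the binomial tolerance band around 95% asserted by the tests.

## Monte Carlo power and sampling adequacy

`mc_power()` estimates the power of a two-sided Mann-Whitney U test
(normal approximation with tie and continuity correction — resampled data
guarantee ties) to detect a multiplicative increase: both groups are drawn
by resampling the empirical base sample with replacement, the treatment
group multiplied by the factor of increase. Bootstrap resampling is the
most direct way to form groups of arbitrary size n from an empirical
base while preserving its shape. The test is two-sided at α = 0.05; a
monitoring program would not know the direction of change in advance.
`n` is per group. One master seed spawns a fixed substream per grid cell,
so any cell can be recomputed in isolation.

Power at factor 1 is an empirical size check (≈ α within Monte Carlo
error); power is monotone in factor and n up to MC jitter; and the package
estimate agrees with an independent brute-force 10,000-rep oracle
implementation of the rank-sum test within 3 combined MC standard errors —
all asserted in the tests. Published headline sample sizes for specific
surveys (e.g. "240 tows for 80% power at a 50% increase") depend on the
survey's own empirical concentration distribution and are not reproducible
from a parametric stand-in; on a clean exponential base the same
comparison yields substantially higher power, which the acceptance report
simply records.

`sample_size_for_power()` smooths the power-vs-n curve by isotonic
regression before thresholding — raw MC curves cross a target power
several times, and the first raw crossing is seed-sensitive.

`adequacy_curve()` asks how much effort a survey needs before its
variability estimate stabilizes: for each n in 2…1000 and 5 independent
sets it draws exponential(rate = 1.44) samples and records the sample SD —
4995 simulated datasets in total, with the SD converging to
1/rate ≈ 0.694 particles m⁻². `fit_exponential_rate()` is the
reciprocal-mean MLE used to derive such a rate from data.

## Size spectra and ocean coverage

`build_spectrum()` places net-measured particle areas and visually sized
macrodebris (diameters through `circle_area()`, items assumed circular) on
one log-spaced cross-sectional-area axis (default 10⁻³–10⁴ cm²), in
consistent per-m² density units, reporting per-bin numeric density and
share of total area. With field-realistic inputs the numerical majority
sits in the smallest bins while the majority of surface area sits in the
large rare items — the canonical micro/macro asymmetry, asserted as an
acceptance property.

`coverage_percent()` is the exact arithmetic
`100 · area_m² / (surveyed_km² · 10⁶)`. Because visual size classes only
bound an item's diameter, `class_bound_coverage()` brackets coverage
between all-items-at-lower-bound and all-items-at-upper-bound; the open
">30 cm" class needs a cap, default 100 cm — items much beyond a metre are
rare enough in visual records that the cap mainly guards the bound against
absurdity, and it is configurable.

## The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume — it is the package's test bed, not an ocean model.

- **Concentration field** (`gen_tows()`): a Gaussian copula. A stationary
  Gaussian process with squared-exponential correlation
  `exp(−(h/range)²)` along a 1-D track (white noise at range 0) is pushed
  through its normal scores into an exponential(rate = 1.44) marginal —
  exact marginals with tunable autocorrelation. Only the marginal fit is
  empirically anchored; the spatial covariance of real debris fields is
  unknown (published debris semivariograms are artifact-prone), so the GP
  is a stand-in, not an inference.
- **Wind availability**: observed concentration = latent ×
  `exp(−decay · max(0, wind − wind_mean))`, reproducing the observation
  that high concentrations occur only in calm conditions. Wind is normal
  (mean 6, SD 2 m s⁻¹, truncated at 0) — typical trade-wind conditions for
  a summer gyre cruise; decay defaults to 0.1 per m s⁻¹, a moderate
  surfacing response.
- **Counts**: Poisson(concentration × swept area); tows record integers.
  Tow area is 780 m × 0.86 m (a 15-minute tow at ~0.87 m s⁻¹ with the
  standard manta mouth). Plastic mass is a Poisson-summed exponential
  (mean 1 mg per particle); zooplankton biomass is lognormal (median
  300 mg, log-SD 0.8), matching the right skew of real biomass.
- **Sightings** (`gen_sightings()`): per segment and group,
  Poisson(density × length × 0.6 km) items uniform in perpendicular
  distance to 600 m, detected with half-normal probability and binned at
  observation time; one-sided transect geometry is hard-coded. Items
  beyond 600 m are not generated — the open bin exists in the schema but
  the generator does not pretend to model horizon detection. Default
  densities (small 60, medium 12, large 3 km⁻², split over colors) and
  scales (σ = 60/150/300 m by size, ±20% by visibility) give the small
  classes numerical dominance and realistic detection falloff.
- **Particles** (`gen_particles()`): exponential areas, rate 100 cm⁻², so
  the modal histogram bin sits near 0.01 cm².

What the generator does *not* emulate: advection and fronts (real fields
are non-stationary), observer fatigue and sea-state effects on detection,
net avoidance/extrusion, diel vertical migration of zooplankton, and
correlated micro/macro patchiness. Passing tests therefore demonstrate
that the estimators are correct under their stated assumptions, not that
those assumptions hold on any particular ocean.

## Numerical conventions and problem sizes

All distances are km internally (bin edges in m where the field protocol
uses metres); concentrations per m², particle areas in cm². Quadrature
tolerances: 1e-8 (ESW), 1e-9 (likelihood bin integrals). WLS convergence
uses L-BFGS-B with factr = 1e4. Underflowing multinomial cells at extreme
parameters return a large finite penalty instead of −Inf so bounded
searches remain well-behaved. Percentile conventions are type 7
throughout.

The test suite exercises the estimators at sizes chosen to make Monte
Carlo bands tight while keeping the full suite near two minutes: n = 5000
for marginal recovery, 400-point tracks × 20 seeds for range recovery,
~2000 detections for σ recovery, 200 surveys × 199 bootstrap replicates
for CI coverage, and 1000–10,000 reps for power comparisons. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities at the same sizes from a single command-line seed.

## Known limitations

- The semivariogram assumes second-order stationarity; a trend in the
  track (e.g. crossing a front) inflates long-lag semivariance and can
  defeat the Gaussian fit.
- Detection fitting ignores sea-state covariates (defensible when
  detectability shows no sea-state trend over Beaufort 0–4, as in calm
  surveys, but not in general).
- Groups with <10 sightings are skipped rather than pooled automatically.
- The power analysis treats tows as exchangeable; spatial autocorrelation
  among tows would make the effective sample size smaller than n.
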