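---
title: "Methods: trend and variability analysis of ocean-color NPP"
author: "oceannpp"
output: rmarkdown::html_document
---

This vignette is the package's account of its science: the statistical model
each stage implements, the assumptions behind it, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The quantity under study

Net primary production (NPP, mg C m⁻² d⁻¹) is modeled throughout as the
product of three satellite-derivable factors,

NPP = PAR × (aφ/a) × φμ,

where PAR is surface photosynthetically active radiation (mol photons m⁻²
d⁻¹), aφ/a the fraction of total absorption attributable to phytoplankton
pigments (dimensionless), and φμ the net photosynthetic carbon efficiency
(mg C per mol absorbed photons). The specific growth rate is μ = NPP /
Cphyto (d⁻¹), with Cphyto the euphotic-zone-integrated phytoplankton carbon
(mg C m⁻²). The package does not compute these fields from reflectances —
spectral NPP modeling and bio-optical inversion happen upstream — it
*consumes* them as monthly gridded series and analyses their joint trends.
`identity_residual()` verifies the multiplicative identity on any input and
reports, rather than hides, violations.

## Pipeline stages and their statistics

### Mission blending

Two missions observing one ocean disagree by persistent, seasonally varying
offsets. `fit_adjustment()` estimates, per cell and calendar month, the mean
difference (reference minus earlier mission) over all collocated overlap
months, requiring at least `min_obs = 3` such months so a single anomalous
month cannot define the correction. The earlier mission is the one adjusted,
the later one the reference, because the later record continues forward and
its radiometric baseline is what subsequent missions will be tied to.
Additive differences (not ratios) are used: differences are exact for any
stationary additive bias, and the property tests exploit that exactness
(a noise-free planted per-month bias is removed identically). Where both
missions observe, the merged record is their mean; cell-months with no
defined adjustment fall back to the unadjusted earlier mission and are
counted, never silently dropped.

Collocated agreement is summarized by Pearson r and the Type-1 (ordinary
least-squares) slope on log10-transformed pairs, since NPP is positive and
approximately log-normal, with a multiplicative mean absolute error
10^mean(|log10(a/b)|). This MAE is dimensionless, symmetric in the two
missions and ≥ 1; a value of 1.04 reads "4% typical multiplicative
disagreement". For signed variables the same statistics are available in
linear space (`log_space = FALSE`).

### Deseasonalization

Monthly anomalies are the data minus the per-cell climatology of their
calendar month (`monthly_climatology()`, `deseasonalize()`). A climatology
month needs `min_count = 5` valid years; fewer and the cell-month stays
missing, which protects high-latitude cells whose winters are rarely
observed from being deseasonalized against a two-sample mean. Per
construction, anomaly means vanish per calendar month over the climatology
window, and the property tests check both this and that >99% of seasonal
harmonic power is removed while planted linear trends survive.

### Per-pixel trends under serial correlation

Trends are fitted by OLS to the anomalies against decimal years at month
centers, reported per decade. Monthly anomalies are serially correlated, so
the OLS slope variance is understated by roughly (1 + ρ)/(1 − ρ) for lag-1
autocorrelation ρ. The package uses the standard first-order correction:

- ρ is the lag-1 Pearson autocorrelation of the *regression residuals*
  (not the raw anomalies, whose trend would inflate ρ);
- n_eff = n (1 − ρ) / (1 + ρ), capped at n so negative sample ρ never
  manufactures information;
- the slope standard error is rescaled by √(n / n_eff) and the two-tailed
  test uses Student's t with df = n_eff − 2 at α = 0.10.

df = n_eff − 2 is the natural small-sample convention (two parameters
estimated); cells where n_eff − 2 < 2 are declared untestable and counted.
Cells need `min_months = 60` valid anomalies — five effective years — below
which polar cells with only a handful of summer observations would dominate
the untestable count. Degenerate series are handled explicitly: residual
sums of squares at machine level (exact lines, constants) are treated as
zero variance, giving ρ = 0, a significant exact line, and a non-significant
constant.

The calibration of this machinery is itself a test: under a no-trend AR(1)
null with ρ = 0.6 and n = 300, the 90% flag fires on 10% ± 2% of 2000
simulated cells, while the uncorrected test fires on well over 15% — the
quantitative reason the correction is not optional.

Normalized trends divide the decadal slope by the cell's mean over the
reference window — by default the first and last complete calendar years of
the record — and are reported in % per decade; |mean| < 10⁻¹⁰ (in the
variable's units) marks the normalization undefined. Area accounting
(`significant_area_fractions()`, `sst_bin_summary()`, `overlap_fraction()`)
always weights by spherical-zone cell areas: fractions are shares of tested
ocean *area*, per-bin distributions are area-weighted percentiles
(10/25/50/75/90 within 1 °C mean-SST bins), and the tests verify that
doubling the latitude resolution leaves every fraction unchanged.

### EOF decomposition

Anomaly fields are first aggregated to a quasi-equal-area grid (latitude
bands of equal height, each split into near-square cells; whole source
cells are assigned by center, which at typical source/target ratios makes
sub-cell splitting negligible and keeps the global area-weighted mean
exactly conserved). Cells with less than 80% temporal coverage are dropped;
remaining gaps are set to the zero anomaly — the minimal-leverage fill,
since a zero anomaly is the column mean and contributes nothing to any
covariance. Columns are re-centered even though anomalies are nominally
centered (gaps induce small offsets), scaled by √area, and decomposed by
SVD. Variance fractions are squared singular values over their total; modes
are returned in anomaly units per unit PC with the weights divided back
out, so PCᵢ(t) · modeᵢ(cell) reconstructs mode i's anomaly field, and the
full-rank reconstruction reproduces the centered matrix to 10⁻⁸.

EOF signs are arbitrary; the package orients each mode so its PC correlates
non-negatively with time, which makes decline-type leading modes read
naturally, and documents the convention in the outputs. PCs are correlated
against monthly climate-index series by plain Pearson correlation on common
months (≥ 24 required), with no smoothing or lagging; the most correlated
index per mode is flagged. A mode's global "range" in Pg C yr⁻¹ is the
max-minus-min of its reconstructed global integral, Σ(mode × area) × PC(t),
converted from mg C d⁻¹ (× 10⁻¹⁸ g/mg-to-Pg, × 365.25 d/yr).

### Global accounting

Monthly global totals integrate NPP × area × true calendar days (leap
Februaries included), converting mg C to Pg C (10⁻¹⁸). Gap filling with the
monthly climatology is applied *only* for global totals and only inside the
sunlit domain, defined by climatological PAR > 1 mol photons m⁻² d⁻¹ —
climatological rather than observed PAR because observed PAR is missing
exactly where filling is needed (polar night, persistent cloud). The filled
area fraction is recorded monthly; unfillable cell-months inside the domain
are counted and warned about. Annual totals use complete calendar years;
the linear fit of annual totals reports slope per decade and a net percent
change defined as 100 × slope × n_years / mean — one of several defensible
conventions (endpoint ratios of the fitted line are another); the choice is
stated here and implemented in exactly one place (`fit_global_trend()`).
The below-mixed-layer fraction is the ratio of global integrals of
below-MLD to total NPP over cells where both are valid.

## The synthetic generator

`generate_dataset()` is the package's laboratory. Per component it builds
climatology(month, latitude) + planted trend × centered time + planted
modes + AR(1) noise, then derives φμ = NPP / (PAR × aφ/a) and μ = NPP /
Cphyto so both identities hold to machine precision, and finally applies
missingness (random cloud loss plus polar night where PAR < 1). Defaults
describe the desk-scale study conditions: a 2° global grid, 300 months from
1997-09, an NPP trend of −30 mg C m⁻² d⁻¹ per decade where mean SST exceeds
15 °C and +20 below (the isotherm where real-world trend signs pivot),
AR(1) ρ = 0.3 with 15 mg C m⁻² d⁻¹ innovations for NPP, 5% cloud loss, and
a sinusoidal per-calendar-month mission bias of −20 ± 10 mg C m⁻² d⁻¹.
AR(1) noise is initialized from its stationary distribution
(SD/√(1 − ρ²)) to avoid burn-in transients that would bias trend tests.
Real anomaly noise magnitudes and spatial covariances are not published
quantities; the defaults were chosen once for test power — strong enough
planted signals to make recovery failures meaningful, weak enough noise
that calibration tests are informative — and are not tuned thereafter.

What the generator deliberately does **not** emulate: spatially correlated
noise (each cell's AR(1) innovations are independent), realistic cloud
morphology, radiative transfer or any spectral structure, eddies/fronts, or
nonlinear trends. Passing tests therefore demonstrate that the *estimators*
are correct and calibrated under the stated statistical structure — they do
not certify performance against, say, spatially coherent noise, where
per-pixel significance counts would have wider sampling variability.

Determinism is a contract: identical configuration and seed give
bit-identical datasets, and the full pipeline under a fixed seed reproduces
every numerical output byte for byte (the frozen config echoes its output
path and the text report carries wall-clock timings; both are excluded from
the byte comparison, and the report's numerical content is compared after
stripping timings).

## Numerical and design choices

- **Earth model**: sphere of radius 6371 km; cell areas are exact spherical
  zones R²Δλ(sin φ₂ − sin φ₁). Reproductions against analyses using an
  ellipsoid may differ below the 0.1% level in area-weighted quantities.
- **Grid conventions**: cell-center registration, latitude −90..90,
  longitude −180..180, matching NASA L3 ocean-color layouts; missing data
  travel as masks (NA), never sentinel values.
- **Record length bookkeeping**: a 300-month default record (1997-09 start)
  has complete years 1998–2021; reference windows default to the first and
  last complete years and are configurable.
- **Tie-breaks and degeneracy**: constant cells report slope 0, not
  significant; ρ estimates from machine-noise residuals are forced to 0;
  sample ρ is capped just below 1 so n_eff stays positive; all silently
  handled degenerate cases (missing climatology, unfillable gaps, undefined
  adjustments, near-zero normalization means, untestable cells) are counted
  in the outputs.
- **Problem sizes**: the shipped tests and the acceptance script run at a
  2°–10° desk scale with 300-month records (e.g. 2000 cells for null
  calibration, 200 replicate cells for coverage, 45 × 90 cells for area
  accounting), sizes chosen so the whole suite exercises every stage in a
  few minutes on one core while keeping Monte-Carlo tolerances meaningful.
  The implementation is resolution-agnostic; 1/12° inputs stream through
  the identical code paths, only slower.

## Known limitations

- No field-significance or multiple-testing control across pixels is
  applied (by design — per-pixel 90% confidence is the reported quantity);
  area fractions of significant trends should be read with that in mind.
- Nonparametric alternatives (Theil–Sen, Mann–Kendall, seasonal Kendall)
  are out of scope; the AR(1)-corrected OLS is the single implemented
  estimator.
- The blending model assumes a stationary per-calendar-month bias; drifting
  inter-mission biases would alias into trends and are not corrected.
- The equal-area aggregation assigns whole source cells by center; at
  source/target ratios near 1 the discretization is no longer negligible
  (choose a target cell several times the source cell size).
- EOF modes are not tested for separability (no North's-rule screening),
  and index attribution is correlational, unlagged and unsmoothed.
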