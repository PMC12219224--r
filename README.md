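# oceannpp

Multi-decadal trend and variability analysis of satellite ocean-color net
primary production (NPP) and its drivers, for biological oceanographers
working with gridded monthly Level-3 fields.

Phytoplankton NPP underpins marine food webs and the biological carbon pump,
and the satellite ocean-color record is the only synoptic, multi-decadal
window on it. Detecting trends in that record requires care on three fronts
that this package automates end to end:

- **Inter-mission bias.** Successive missions (e.g. SeaWiFS then MODIS-Aqua)
  carry persistent radiometric offsets. The earlier mission is harmonized to
  the later one by *per-calendar-month climatology differences* fitted over
  their overlap, then the two are averaged where both observe.
- **Serial correlation.** Monthly anomalies are strongly autocorrelated, so
  naive per-pixel ordinary least squares wildly overstates significance. The
  package fits OLS trends to deseasonalized anomalies and corrects the
  slope's uncertainty with the first-order effective sample size

  n_eff = n (1 − ρ) / (1 + ρ),

  where ρ is the lag-1 autocorrelation of the regression residuals. The
  slope standard error is rescaled by √(n / n_eff) and significance assessed
  by a two-tailed t test with df = n_eff − 2 at α = 0.10 (90% confidence).
- **Area weighting.** All fractions, means, percentile summaries and global
  integrals weight cells by their spherical-zone areas, and the EOF
  (empirical orthogonal function) decomposition of anomaly fields runs on a
  quasi-equal-area grid so meridian convergence cannot masquerade as
  variance structure.

Around that statistical core sit the absorption-based NPP decomposition
(NPP = PAR × aφ/a × φμ, with growth rate μ = NPP / Cphyto), global annual
totals with climatological gap filling restricted to the sunlit domain
(climatological PAR > 1 mol photons m⁻² d⁻¹), SST-binned trend summaries,
principal-component attribution against climate-index series, and the
fraction of production beneath the surface mixed layer.

A first-class synthetic-ocean generator produces multi-year gridded datasets
with *known* planted truth — latitude-dependent seasonal cycles, linear
trends whose sign flips across a mean-SST isotherm, AR(1) noise, planted
spatial modes driven by index series, cloud/polar-night missingness and a
stationary per-month mission bias — so every stage is testable without any
downloads.

## Worked example

A complete synthetic run on a 6° desk-scale grid (30 × 60 cells, 300 months
from 1997-09, two biased missions, two planted anomaly modes):

```r
library(oceannpp)
cfg <- default_pipeline_config(out_dir = "readme_run", seed = 42)
cfg$synthetic$res_deg <- 6
report <- run_pipeline(cfg)
```

which writes netCDF trend maps, the blend adjustment, EOF modes/PCs, CSV
summary tables and a report under `readme_run/`. The printed report:

```
== ocean NPP pipeline report ==
seed: 42

blend: r = 0.999, slope = 0.946, MAE factor = 1.043

significant-trend area fractions (of tested ocean area):
  npp       neg  64.5% (  -30.7 /decade,   -5.1 %/decade)  pos  35.5% (   20.7 /decade,    4.5 %/decade)
  par       neg   5.9% ( -0.298 /decade,   -0.9 %/decade)  pos   5.6% (  0.326 /decade,    1.0 %/decade)
  aph_frac  neg  99.3% (-0.00396 /decade,   -1.2 %/decade)  pos   0.0% (     NA /decade,     NA %/decade)
  ...
overlap of significant NPP and aph/a trends: decreasing 99%, increasing 0%

EOF variance fractions: 53.2%, 7.9%, 5.5%, 0.4%; PC1 global range 4.30 Pg C yr-1
  mode 2 best index: planted_mode2 (r = 0.96)

global NPP: mean 65.8 +/- 1.1 Pg C yr-1; trend -1.54 Pg C decade-1 (net -5.6%); below-MLD fraction 0.291
```

Reading it: the collocated mission comparison is tight (log-space r = 0.999)
with a 4.3% multiplicative mean absolute error before harmonization; NPP
declines significantly over 64.5% of the tested ocean at −30.7 mg C m⁻² d⁻¹
per decade (−5.1% of the local mean per decade), mirroring the planted
warm-water decline; the fraction of absorbed light captured by phytoplankton
(aφ/a) carries the commensurate decline (99% spatial overlap); the leading
EOF mode is the planted trend pattern while mode 2 recovers its planted
index at r = 0.96; and the synthetic globe loses NPP at 1.54 Pg C per decade
with 29% of production beneath the mixed layer.

The same pipeline runs on real mission archives by setting
`cfg$synthetic$enabled <- FALSE` and pointing `cfg$inputs` at CF-style
netCDF files (monthly fields with `lat`/`lon`/`time` coordinates and units
attributes).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/npp-pipeline.R run-all --seed 42 --out run_dir
```

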