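Package: oceannpp
Title: Trend and Variability Analysis of Satellite Ocean-Color Net Primary Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-decadal trend analysis of gridded monthly ocean-color
    fields: inter-mission bias blending via per-calendar-month climatology
    differences, deseasonalization against monthly climatologies, per-pixel
    ordinary least-squares trends with AR(1) effective-sample-size corrected
    significance, area-weighted accounting of significant trends and
    sea-surface-temperature binned summaries, empirical orthogonal function
    decomposition of anomaly fields on an equal-area grid with climate-index
    attribution, absorption-based decomposition of net primary production into
    its atmospheric, bio-optical and physiological drivers, global annual
    totals with climatological gap filling, and the below-mixed-layer
    production fraction. Includes a synthetic gridded-ocean generator with
    known planted truth (trends, modes, mission bias, AR(1) noise,
    missingness) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
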