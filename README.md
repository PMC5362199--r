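# lichentrend

Terricholous lichen mats — ground-dwelling *Cladonia* lichens — are the
dominant winter forage of barren ground caribou (*Rangifer tarandus
groenlandicus*). `lichentrend` is an R package for the remote-sensing
workflow that tracks the condition of those mats through time and asks
whether caribou movement responds to it:

1. **Score lichen volume per pixel and year.** From green/NIR/SWIR1 surface
   reflectance, compute the NDLI `(SWIR1 − green)/(SWIR1 + green)` and NDMI
   `(NIR − SWIR1)/(NIR + SWIR1)` indices and combine them in a correlated
   two-dimensional Gaussian, the lichen volume estimate (LVE):
   `LVE = A·exp(−(u² − 2ρuv + v²) / (2(1 − ρ²)))` with standardized index
   deviations `u`, `v` about a fixed or scene-mean center. LVE is a
   relative index; its calibration constants are explicit configuration.
2. **Detect temporal change per pixel** with Theil–Sen slopes (median of
   all pairwise slopes) and tie-corrected, continuity-corrected
   Mann–Kendall tests at `alpha = 0.05`.
3. **Find spatial clusters of change** with the Getis–Ord G\* statistic on
   a 3×3 Queen's-case kernel (self-inclusive, binary weights, global
   mean/sd over all valid pixels), classified two-sided at `z = 1.96`.
4. **Compare herd ranges**: zonal class percentages per herd polygon,
   spatially stratified sampling of the slope raster (1000 pixels per
   herd), a single-factor GLS with a Gaussian spatial correlation structure
   `corr(d) = exp(−(d/r)²)` chosen by likelihood ratio against independent
   errors, and Tukey HSD pairwise comparisons.
5. **Relate movement to lichen**: GPS-telemetry QC (a complete year at ≥ 3
   fixes/day), step velocities (haversine distance / elapsed hours, mixed
   5 h and 8 h collars), season assignment, 95% minimum convex polygon
   ranges, LVE extraction at fix locations, and per-season
   negative-binomial additive models `log E[v] = s(LVE) + b_animal` with
   penalized B-spline smooths and per-animal random intercepts (mgcv).

Because real composite imagery and telemetry of this kind are not freely
shippable, the package includes a first-class synthetic-data module:
reflectance scenes built by *inverting* the LVE pipeline (so planted trends
are recovered to machine precision in the noise-free case) and
correlated-random-walk tracks whose step lengths respond to the local LVE
with configurable seasonal shapes. Every analysis stage is tested against
that planted truth.

## Worked example

```r
library(lichentrend)

rec    <- scene_recipe(n_rows = 64, n_cols = 64, years = 1984:2012, seed = 7)
scene  <- make_scene(rec)                      # stack + mask + herd polygons + truth
lve    <- lve_stack(scene$stack, scene$mask, rec$params)
trends <- trend_raster(lve, alpha = 0.05)
trends
#> <trend_raster> 64 x 64, 29 years, alpha 0.05
#>   increasing 200 | decreasing 186 | no_change 3325 | invalid 385

clusters <- gi_star(slope_raster(trends))
clusters
#> <hotspot_raster> 64 x 64, z_crit 1.96
#>   positive 167 | negative 153 | none 3391 | invalid 385

zonal_class_percentages(trends, scene$mask, scene$ranges)
#> # A tibble: 6 × 4
#>   herd_id class      n_pixels   pct
#> 1 west    increasing       46  2.58
#> 2 west    decreasing      143  8.01
#> 3 west    no_change      1597 89.4
#> 4 east    increasing      152  8.41
#> 5 east    decreasing       40  2.21
#> 6 east    no_change      1616 89.4

samples <- stratified_sample(slope_raster(trends), scene$ranges, n = 500, seed = 7)
fit <- gls_herd_model(samples)                 # ML, Gaussian spatial correlation
fit
#> <gls_herd_fit> 2 herds, 1000 samples, errors: gaussian
#>   L.Ratio = 1029.97 (p = 2.21e-224), range = 160.6 m
#>   herd F = 2.175 (p = 0.141)
tukey_pairwise(fit)
#> # A tibble: 1 × 7
#>   contrast    estimate std_error    df t_ratio adj_p_value significant
#> 1 east - west   0.0347    0.0235   996    1.47       0.141 FALSE
```

Reading the output: the scene was planted with clusters of decreasing
trends (−0.5 LVE/yr) in the western herd polygon and increasing trends
(+0.5 LVE/yr) in the eastern one, over a noisy zero-trend background. The
trend stage classifies about 5% of background pixels as changing (the
nominal false-positive rate) plus the planted clusters; the zonal table
shows the planted asymmetry (west 8.0% decreasing vs 2.2% east; east 8.4%
increasing vs 2.6% west). The likelihood ratio (1029.97) says the sampled
slopes are strongly spatially correlated, so the herd comparison must use
the spatial GLS — which, correctly, does not call a 0.035 LVE/yr difference
in herd means significant once that correlation is accounted for
(`p = 0.141`); the independence model would. `tidy()`, `glance()` and
`autoplot()` methods exist for the fitted objects, and `run_all()` executes
the whole chain (plus the movement stages) from one `pipeline_config()`,
writing rasters, CSV tables and a checksummed manifest.

The movement side works the same way:

```r
tracks <- make_tracks(track_recipe(n_animals = 8, years = 2008:2009, seed = 1), lve)
steps  <- extract_lve_at_fixes(step_velocities(qc_filter(tracks)), lve)
fit_w  <- fit_velocity_smooth(dplyr::filter(steps, season == "winter"))
autoplot(fit_w)    # mean predicted velocity vs LVE, ± 1 SE
```

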