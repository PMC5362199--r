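---
title: "Methods: lichen volume trends and caribou movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lichen volume trends and caribou movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lichentrend)
```

# The problem

Terricholous lichen mats (chiefly *Cladonia*) are the dominant winter forage
of barren ground caribou. This package implements a desk-scale, fully
testable version of a remote-sensing workflow for asking two questions:

1. **Where and how has lichen mat volume changed** over a multi-decade
   series of annual Landsat-style surface-reflectance composites?
2. **How do caribou movement rates respond** to the lichen volume a raster
   assigns to the places they move through, season by season?

Every stage operates on synthetic data generated by the package itself, with
known ground truth, so each statistical claim the pipeline makes can be
checked against what was planted.

# The lichen volume estimate (LVE)

Two normalized-difference indices are computed per pixel from three semantic
bands (`green`, `nir`, `swir1`):

- NDLI = (SWIR1 − green) / (SWIR1 + green)
- NDMI = (NIR − SWIR1) / (NIR + SWIR1)

A note on band semantics: the NDMI used here is the standard
(NIR − SWIR)/(NIR + SWIR) form, so the package requires an `nir` band.
Band labels are supplied by configuration and never guessed from file
metadata.

The LVE scores each pixel with a correlated two-dimensional Gaussian over
the (NDLI, NDMI) plane:

$$\mathrm{LVE} = A \exp\!\left(-\frac{u^2 - 2\rho u v + v^2}{2(1-\rho^2)}\right),
\qquad u = \frac{\mathrm{NDLI}-c_1}{\sigma_1},\;
v = \frac{\mathrm{NDMI}-c_2}{\sigma_2}.$$

**Parameters.** The calibrated coefficients of the original Norwegian
in-situ fit are not published in a reusable form, so `lve_params()` ships
**placeholder defaults** (amplitude `A = 100`, centers 0, spreads 0.25,
`rho = 0`) and treats the whole set as mandatory configuration. All outputs
are a *relative* index; no conversion to physical volume is attempted, and
none should be read into the numbers.

**Centering.** `center_mode = "scene_mean"` (the default) re-centers the
Gaussian per year on the scene-wide mean indices over the lichen mask;
whether such means should be per-year or series-wide is genuinely open, so
`center_scope = "stack"` provides the single-mean alternative.
`center_mode = "fixed"` uses the configured centers and is what the
synthetic-data recipes require (see below).

# Trend detection

For each pixel's valid-year series the package computes

- the **Theil–Sen slope**: the median of all pairwise slopes
  \((x_j - x_i)/(t_j - t_i)\), robust to outliers;
- the **Mann–Kendall test**: \(S = \sum_{i<j} \mathrm{sign}(x_j - x_i)\)
  with the tie-corrected variance
  \(\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_k t_k(t_k-1)(2t_k+5)]/18\) and a
  continuity-corrected z-score; a fully tied series reports `p = 1` rather
  than erroring.

Pixels are classified `increasing` / `decreasing` / `no_change` at
`alpha = 0.05`, per pixel, with **no multiple-testing correction** — the
per-pixel convention of the trend-mapping literature this follows. A
Benjamini–Hochberg option (`p_adjust = "fdr"`) exists but is off by default.
Tie and continuity corrections, and the `min_years = 10` completeness rule,
are this package's documented choices; quantized reflectance makes ties a
real possibility, which is why the tie term is not optional.

# Local clusters of change (G\*)

The Getis–Ord statistic with self-inclusion is applied to the slope raster
on a 3×3 Queen's-case kernel with binary weights:

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar X W_i}
{S\sqrt{\left(n W_i - W_i^2\right)/(n-1)}},$$

where \(\bar X\) and \(S\) (denominator \(n\)) are computed **once over all
valid pixels of the raster** — each neighbourhood is judged against the
whole image. The kernel truncates at edges and nodata; \(W_i\) is the count
of valid neighbours actually present. The global statistics are taken over
valid (lichen-mask) pixels only, a choice the package documents because the
alternative (including non-lichen pixels) is defensible but less coherent
with the masked analysis. Classification is two-sided at `z_crit = 1.96`.

# Herd-range comparison

Zonal summaries count classified lichen pixels whose **cell center** falls
in each herd polygon (ties to the first polygon in file order — a
deterministic rule). Percentages are over classified pixels, so each herd's
three classes sum to 100 by construction; the test suite verifies the counts
against an independent recount.

For the formal comparison, `stratified_sample()` draws `n = 1000` pixels per
herd: the polygon's bounding box is cut into a ⌈√n⌉² grid of strata and
draws are allocated proportionally to each stratum's eligible-pixel count
(largest-remainder rounding), uniformly without replacement within strata.
The "spatially stratified" phrasing in the source analysis is not specified
further; this grid scheme is the package's concrete choice, and all valid
slope pixels are eligible (significant or not).

`gls_herd_model()` then fits `slope ~ herd` by ML, with and without a
Gaussian spatial correlation structure
\(\mathrm{corr}(d) = \exp(-(d/r)^2)\) (nugget on by default — the nlme-style
practice that also stabilises convergence on noisy fields), reports the
likelihood-ratio statistic between the two, and the herd F test of the
spatial model. Tukey HSD pairwise comparisons use the studentized range
with the GLS effective residual degrees of freedom via emmeans — the
closest defensible analogue for a GLS fit. The semivariogram check that
often precedes such models is provided as a diagnostic utility
(`residual_semivariogram()`), not a gating stage; the LR comparison is the
scriptable model choice.

**Why the correlation structure matters** is demonstrated rather than
asserted: under a null simulation (equal herd means over a spatially
correlated field, `simulate_herd_samples()`), the independence model
rejects far above its nominal 5% while the spatial model stays calibrated.
The simulation's conditions — three adjacent 10 km herd blocks, 49
grid-stratified samples each, correlogram range 800 m with a 0.2 nugget —
were chosen once as a realistic sampling regime in which the model's
assumptions hold exactly; the acceptance suite runs 500 replicates of it.

# Movement and seasonal association

Telemetry QC keeps animals with ≥ 365 consecutive days at ≥ 3 fixes/day.
Velocity (m/h) is the movement metric because collars mix 5 h and 8 h fix
intervals; distances are haversine on a 6,371 km sphere, steps longer than
9 h (8 h nominal + 1 h tolerance) are dropped. The season calendar
(spring Apr 16 – Jun 7, summer Jun 8 – Sep 7, fall Sep 8 – Nov 30, winter
Dec 1 – Apr 15) is this package's configurable convention bracketing
calving and rut; the exact boundaries of the source analyses are not
published. The LVE covariate is read at the **start fix** of each step
(simplest deterministic convention; a midpoint option was considered and
rejected as adding a projection step without changing any conclusion at
30 m cells), and steps are not split across season boundaries.

`fit_velocity_smooth()` fits, per season,
\(v \sim \mathrm{NB}(\mu, \theta)\),
\(\log \mu = s(\mathrm{LVE}) + b_{\mathrm{animal}}\), in mgcv: a cubic
B-spline basis (`k = 8`) with second-difference penalty selected by ML, and
per-animal random intercepts as a penalized ridge smooth. Velocities are
rounded to integer m/h to admit the count family — the source describes a
"negative binomial link" applied to velocities without saying how they were
discretized, so the rounding is stated here as the package's convention
(at caribou speeds the rounding error is < 1%). Residual spatial
correlation is **not** modelled inside the GAMM: a spatially correlated
NB-GAMM is heavy and under-specified by its source; the association
contract (curve shape ± SE) is preserved and residual structure can be
inspected with the semivariogram utility. This is a known limitation.

Prediction (`predict_curve()`) is at the population level (random
intercepts zero) with delta-method standard errors; figures show mean ± 1 SE.

# The synthetic-data generators

The generators *invert the analysis model* rather than simulating radiative
transfer — the point is that the pipeline's assumptions hold exactly, so
recovery tests are sharp and any failure is an implementation defect, not
model mismatch.

**Scenes** (`make_scene()`): a per-year target LVE field is built as
baseline + planted cluster trends × elapsed years + Gaussian noise, then
mapped back to reflectance: each target LVE is placed on the matching level
set of the LVE Gaussian along a fixed per-pixel direction, and each
(NDLI, NDMI) pair is solved to a band triple in (0, 1) reproducing it to
machine precision. The default scene is 128 × 128 pixels at 30 m over
29 annual composites, lichen fraction 0.9, baseline LVE 30, noise sd 1
LVE/yr-observation, and four circular clusters of ±0.5 LVE/yr (negative in
the western herd polygon, positive in the eastern). The inversion requires
`center_mode = "fixed"` — scene-mean centering would make the construction
circular, since the center would depend on every pixel being constructed.
Ground truth ships with the scene: the slope raster, cluster signs, and a
zone raster separating cluster interiors (2 cells in from the edge) from
background (more than 3 cells from any cluster) for sensitivity scoring.

At these default conditions the Theil–Sen sampling error per pixel is about
0.023 LVE/yr (noise sd 1 over 29 years), so the planted-slope recovery
bound of 0.02 median absolute error is a genuine test of correctness, not
slack.

**Tracks** (`make_tracks()`): one correlated random walk per animal — step
velocity ~ negative binomial with mean set by the current season's response
to the LVE in the animal's cell, wrapped-normal turning angles, reflection
at the raster boundary, fixes at 5 h or 8 h intervals over whole calendar
years (so every simulated animal passes QC by construction). Response
shapes (`season_response()`): flat, linear decline, threshold decline, and
u-shape, mirroring the qualitative seasonal patterns the association stage
should distinguish. `simulate_step_table()` is the walk-free counterpart —
LVE drawn uniformly, log-normal animal intercepts, NB velocities — i.e.
exactly the generative model the GAMM assumes, used for the
replicated shape-recovery and calibration experiments where the walk would
only add runtime.

**What the generators do not emulate:** sensor noise models, clouds and
compositing artefacts, topography, land-cover change in the mask,
behavioural states, and insect or snow covariates. Passing recovery tests
therefore show the *statistics are implemented correctly and have the
claimed operating characteristics under their own assumptions* — not that
real Landsat composites or real caribou meet those assumptions.

A geometric caveat of the same kind: telemetry lon/lat are related to
raster coordinates by a local equirectangular tangent plane
(`local_projection()`). Within the desk-scale scenes (a few km around the
reference point) it agrees with great-circle distances to well under 0.1%;
it is not a substitute for a proper projected CRS at continental extents.

# Numerical choices and degenerate inputs

- Rasters are exchanged as plain-text ESRI ASCII grids with a `.prj`
  sidecar; values are printed with 17 significant digits so write/read
  round-trips are bit-exact. Geographic (degree-unit) CRSs are rejected at
  construction: kernels and zonal sampling assume uniform cell area.
- Nearest-neighbour mask resampling is defined by cell-center lookup, which
  stays well-defined for non-integer resolution ratios (e.g. 250 m → 30 m).
- A zero index denominator yields an invalid pixel, never an error; a fully
  tied series yields `p = 1`; an all-equal slope raster is a degenerate
  input for G\* and errors loudly.
- All randomness flows from explicit seeds; recipe seeds are split into
  per-stage streams (`mask`, `directions`, `noise`, `tracks`) so adding a
  stage never shifts another stage's draws.
- `run_all()` writes a manifest of inputs, config hash, seeds and output
  checksums. Stage timings go to a separate run log so that manifests are
  byte-identical across reruns of the same configuration — reproducibility
  is checked by hashing, not by eye.

# Problem sizes

The shipped experiments use sizes chosen so the whole suite runs on a
laptop-class machine: the 128 × 128 × 29 default scene for end-to-end
recovery; 2,000 white-noise replicates (n = 29) for Mann–Kendall
calibration; 500 replicates of the GLS null simulation (147 samples each);
100 replicates × 4 response shapes (600 steps, 5 animals) for the
association stage; and exhaustive enumeration of all 1,053 short tied
series for the Mann–Kendall oracle. The real study this workflow is modelled
on processed ~700,000 km² and hundreds of thousands of GPS fixes; nothing
in the code caps the problem size, but tiling and parallelism for
continental extents are out of scope.

# Known limitations

- LVE coefficients are placeholders; absolute levels are meaningless until
  calibrated against in-situ lichen volume.
- No spatial correlation inside the seasonal GAMM (documented above).
- Simple polygons only (no holes) for herd ranges; one polygon per herd.
- The local projection is for desk-scale scenes; use proper projected
  rasters for real data.
- Serial correlation within a pixel's time series is not pre-whitened; the
  Mann–Kendall test assumes exchangeable errors, as in the workflow it
  reimplements.
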