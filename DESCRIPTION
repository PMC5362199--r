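Package: lichentrend
Title: Lichen Volume Trends and Caribou Movement from Annual Reflectance Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise assessment of terricholous lichen mat condition and its
    consequences for barren ground caribou movement. Computes a relative lichen
    volume estimate (LVE) per pixel and year from green/NIR/SWIR1 surface
    reflectance via two spectral indices (NDLI, NDMI) combined in a correlated
    two-dimensional Gaussian; detects temporal change with per-pixel Theil-Sen
    slopes and tie-corrected Mann-Kendall tests; finds local clusters of change
    with the Getis-Ord Gi* statistic on a Queen's-case kernel; summarises and
    compares change across herd ranges with zonal class percentages, spatially
    stratified sampling, generalized least squares with a Gaussian spatial
    correlation structure, and Tukey HSD; and relates GPS-telemetry movement
    velocities to LVE with seasonal negative-binomial additive mixed models.
    Includes a synthetic-data generator (invertible reflectance scenes with
    planted trends and clusters; correlated-random-walk tracks with
    LVE-dependent step lengths) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
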