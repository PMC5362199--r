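#' Recipe for a synthetic reflectance scene
#'
#' Describes a desk-scale stand-in for the study inputs: an annual
#' green/NIR/SWIR1 reflectance stack whose derived LVE fields carry
#' spatially clustered linear trends plus Gaussian noise, a lichen mask, and
#' herd polygons with distinct planted trend mixes. The default scene is
#' 128 x 128 pixels at 30 m over 29 annual composites (the 1984-2012 span at
#' toy extent), baseline LVE 30, pixel noise sd 1 LVE unit, and four planted
#' circular clusters of slope +/- 0.5 LVE/yr (negative in the western herd,
#' positive in the eastern herd).
#'
#' @param n_rows,n_cols Grid size in cells.
#' @param cell_size Cell size in metres.
#' @param years Integer years of the annual stack.
#' @param lichen_fraction Proportion of cells flagged lichen tundra.
#' @param clusters A tibble `row`, `col`, `radius` (cells), `trend`
#'   (LVE/yr); `NULL` for the default layout scaled to the grid.
#' @param baseline_lve Baseline LVE at the first year: a scalar for a flat
#'   baseline, or `c(lo, hi)` for a smooth diagonal gradient across the
#'   scene (useful when downstream stages need a wide LVE range).
#' @param noise_sd Per-pixel, per-year Gaussian noise sd in LVE units.
#' @param nodata_fraction Fraction of (year, cell) observations punched out
#'   as nodata (default 0).
#' @param params [lve_params()] used for the inversion; must be `fixed`
#'   center mode (scene-mean centering would make the inversion circular).
#' @param lon0,lat0 Geographic anchor of the scene center (Northwest
#'   Territories tundra by default), defining the local projection.
#' @param seed Master seed; all scene randomness derives from it.
#' @return An object of class `scene_recipe`.
#' @export
scene_recipe <- function(n_rows = 128, n_cols = 128, cell_size = 30,
                         years = 1984:2012, lichen_fraction = 0.9,
                         clusters = NULL, baseline_lve = 30, noise_sd = 1,
                         nodata_fraction = 0,
                         params = lve_params(center_mode = "fixed"),
                         lon0 = -115, lat0 = 65, seed = 1L) {
  stopifnot(noise_sd >= 0, lichen_fraction >= 0, lichen_fraction <= 1,
            nodata_fraction >= 0, nodata_fraction < 1,
            inherits(params, "lve_params"))
  if (params$center_mode != "fixed") {
    stop("scene_recipe: params must use center_mode = 'fixed' (the inversion ",
         "targets a known Gaussian center)", call. = FALSE)
  }
  if (is.null(clusters)) {
    clusters <- tibble::tibble(
      row = round(c(0.25, 0.70, 0.30, 0.72) * n_rows),
      col = round(c(0.25, 0.30, 0.75, 0.72) * n_cols),
      radius = round(c(0.08, 0.06, 0.08, 0.06) * min(n_rows, n_cols)),
      trend = c(-0.5, -0.5, 0.5, 0.5)
    )
  }
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("row", "col", "radius", "trend") %in% names(clusters)))
  if (any(clusters$row - clusters$radius < 1 |
          clusters$row + clusters$radius > n_rows |
          clusters$col - clusters$radius < 1 |
          clusters$col + clusters$radius > n_cols)) {
    stop("recipe error: clusters must lie within the grid", call. = FALSE)
  }
  stopifnot(length(baseline_lve) %in% 1:2, all(baseline_lve > 0))
  span <- diff(range(years))
  peak <- max(baseline_lve) + max(abs(clusters$trend)) * span + 6 * noise_sd
  if (peak >= params$amplitude) {
    stop("recipe error: planted trends can push target LVE above the ",
         "Gaussian amplitude (", round(peak, 1), " >= ", params$amplitude, ")",
         call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         years = as.integer(years), lichen_fraction = lichen_fraction,
         clusters = clusters, baseline_lve = baseline_lve,
         noise_sd = noise_sd, nodata_fraction = nodata_fraction,
         params = params, lon0 = lon0, lat0 = lat0, seed = as.integer(seed)),
    class = "scene_recipe"
  )
}

# Solve (ndli, ndmi) on the level set of the LVE Gaussian that scores
# `target`, walking from the center along per-pixel direction `theta`.
invert_lve <- function(target, theta, params) {
  q <- -2 * log(target / params$amplitude)  # quadratic form value, >= 0
  rho <- params$rho
  t2 <- q * (1 - rho^2) / (1 - rho * sin(2 * theta))
  t <- sqrt(pmax(t2, 0))
  list(ndli = params$mu_ndli + params$sigma_ndli * t * cos(theta),
       ndmi = params$mu_ndmi + params$sigma_ndmi * t * sin(theta))
}

# Solve a (green, nir, swir1) reflectance triple in (0, 1) reproducing the
# two indices exactly: pick swir1 below its feasibility bound, then back out
# the other two bands from the index definitions.
bands_from_indices <- function(ndli, ndmi) {
  s <- 0.9 * pmin(1, (1 + ndli) / (1 - ndli), (1 - ndmi) / (1 + ndmi))
  list(green = s * (1 - ndli) / (1 + ndli),
       nir = s * (1 + ndmi) / (1 - ndmi),
       swir1 = s)
}

#' Generate a synthetic scene by inverting the LVE pipeline
#'
#' Builds a per-year target LVE field (baseline + planted cluster trends
#' times elapsed years + Gaussian noise), then inverts the analysis model:
#' each target LVE is mapped to an (NDLI, NDMI) pair on the matching level
#' set of the LVE Gaussian (along a fixed per-pixel direction, so a pixel's
#' trend traces a smooth path in index space), and each index pair to a
#' reflectance triple reproducing it exactly. Because the generator inverts
#' the model rather than simulating radiative transfer, recomputing LVE from
#' the emitted reflectance recovers the planted field to machine precision —
#' which is what makes downstream recovery tests sharp.
#'
#' Ground truth carried alongside: the planted slope raster, the cluster
#' sign raster, and a zone raster separating cluster `interior` (2 cells in
#' from the cluster edge), `edge`, and `background` (more than 3 cells from
#' any cluster) for sensitivity/false-positive scoring.
#'
#' @param recipe A [scene_recipe()].
#' @return A list of class `synthetic_scene`: `stack`
#'   ([reflectance_stack()]), `mask` ([lichen_mask()]), `ranges`
#'   ([herd_ranges()]; western herd holds the negative clusters, eastern the
#'   positive), `truth` (list `slope`, `cluster`, `zone`), `recipe`.
#' @export
make_scene <- function(recipe) {
  stopifnot(inherits(recipe, "scene_recipe"))
  nr <- recipe$n_rows; nc <- recipe$n_cols
  npx <- nr * nc
  proj <- local_projection(recipe$lon0, recipe$lat0)
  g <- grid_spec(nr, nc, recipe$cell_size,
                 origin_x = -nc * recipe$cell_size / 2,
                 origin_y = nr * recipe$cell_size / 2,
                 crs_id = proj$crs_id)

  mask_m <- with_seed(split_seed(recipe$seed, 1), {
    matrix(stats::runif(npx) < recipe$lichen_fraction, nr, nc)
  })
  theta <- with_seed(split_seed(recipe$seed, 2), {
    matrix(stats::runif(npx, 0, 2 * pi), nr, nc)
  })

  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  slope_m <- matrix(0, nr, nc)
  cluster_m <- matrix(0L, nr, nc)
  mind <- matrix(Inf, nr, nc)  # distance to nearest cluster edge (cells)
  for (k in seq_len(nrow(recipe$clusters))) {
    ck <- recipe$clusters[k, ]
    d <- sqrt((rowm - ck$row)^2 + (colm - ck$col)^2)
    inside <- d <= ck$radius
    slope_m[inside] <- ck$trend
    cluster_m[inside] <- as.integer(sign(ck$trend))
    mind <- pmin(mind, d - ck$radius)
  }
  zone_m <- matrix("background", nr, nc)
  zone_m[mind <= 3] <- "edge"
  zone_m[mind <= -2] <- "interior"

  bl <- recipe$baseline_lve
  baseline_m <- if (length(bl) == 2) {
    bl[1] + (bl[2] - bl[1]) * ((rowm - 1) + (colm - 1)) / (nr + nc - 2)
  } else {
    matrix(bl, nr, nc)
  }

  years <- recipe$years
  y0 <- years[1]
  amp <- recipe$params$amplitude
  vals <- array(NA_real_, c(length(years), 3, nr, nc),
                dimnames = list(NULL, c("green", "nir", "swir1"), NULL, NULL))
  noise <- with_seed(split_seed(recipe$seed, 3), {
    array(stats::rnorm(length(years) * npx, 0, recipe$noise_sd),
          c(length(years), nr, nc))
  })
  for (iy in seq_along(years)) {
    target <- baseline_m + slope_m * (years[iy] - y0) +
      matrix(noise[iy, , ], nr, nc)
    target <- pmin(pmax(target, 0.5), 0.999 * amp)
    idx <- invert_lve(target, theta, recipe$params)
    if (max(abs(idx$ndli), abs(idx$ndmi)) > 0.97) {
      stop("recipe error: inverted indices leave the representable range; ",
           "reduce trends/noise or widen sigma", call. = FALSE)
    }
    bb <- bands_from_indices(idx$ndli, idx$ndmi)
    # non-lichen cells get a fixed benign spectrum
    for (b in names(bb)) {
      bench <- c(green = 0.10, nir = 0.30, swir1 = 0.20)[[b]]
      m <- bb[[b]]
      m[!mask_m] <- bench
      vals[iy, b, , ] <- m
    }
  }
  if (recipe$nodata_fraction > 0) {
    holes <- with_seed(split_seed(recipe$seed, 4), {
      which(matrix(stats::runif(length(years) * npx), length(years)) <
              recipe$nodata_fraction, arr.ind = TRUE)
    })
    for (h in seq_len(nrow(holes))) {
      cell <- arrayInd(holes[h, 2], c(nr, nc))
      vals[holes[h, 1], , cell[1], cell[2]] <- NA_real_
    }
  }

  half_w <- -recipe$cell_size  # western herd: columns left of center, inset
  xmin <- g$origin_x; xmax <- g$origin_x + nc * recipe$cell_size
  ymin <- g$origin_y - nr * recipe$cell_size; ymax <- g$origin_y
  ranges <- herd_ranges(tibble::tibble(
    herd_id = rep(c("west", "east"), each = 4),
    x = c(xmin, half_w, half_w, xmin,
          recipe$cell_size, xmax, xmax, recipe$cell_size),
    y = c(ymin, ymin, ymax, ymax, ymin, ymin, ymax, ymax)
  ), crs_id = g$crs_id)

  structure(
    list(stack = reflectance_stack(g, years, vals),
         mask = lichen_mask(g, mask_m),
         ranges = ranges,
         truth = list(slope = scalar_raster(g, slope_m),
                      cluster = cluster_m, zone = zone_m),
         recipe = recipe),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d x %d years, %d planted cluster(s), noise sd %.3g\n",
    x$recipe$n_rows, x$recipe$n_cols, length(x$recipe$years),
    nrow(x$recipe$clusters), x$recipe$noise_sd))
  invisible(x)
}
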