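# Shared fixtures, built in code at test time.

# A tiny fully-valid scalar raster with known values.
toy_raster <- function(vals = matrix(1:9, 3, 3), cell = 30, crs = "EPSG:3978") {
  g <- grid_spec(nrow(vals), ncol(vals), cell, crs_id = crs)
  scalar_raster(g, matrix(as.numeric(vals), nrow(vals), ncol(vals)))
}

# Hand-buildable reflectance stack: one matrix per band per year.
toy_stack <- function(years, band_fn, n = 3, cell = 30) {
  g <- grid_spec(n, n, cell, crs_id = "EPSG:3978")
  vals <- array(NA_real_, c(length(years), 3, n, n),
                dimnames = list(NULL, c("green", "nir", "swir1"), NULL, NULL))
  for (iy in seq_along(years)) {
    b <- band_fn(years[iy])
    for (nm in c("green", "nir", "swir1")) vals[iy, nm, , ] <- b[[nm]]
  }
  reflectance_stack(g, years, vals)
}

all_true_mask <- function(grid) {
  lichen_mask(grid, matrix(TRUE, grid$n_rows, grid$n_cols))
}

# Independent brute-force Theil-Sen: explicit double loop over pairs.
ts_bruteforce <- function(x, t = seq_along(x)) {
  sl <- c()
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      if (j > i) sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
    }
  }
  median(sl)
}

# Independent direct-summation Mann-Kendall oracle.
mk_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  tie_term <- 0
  for (v in unique(x)) {
    tk <- sum(x == v)
    if (tk > 1) tie_term <- tie_term + tk * (tk - 1) * (2 * tk + 5)
  }
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term) / 18
  if (var_s <= 0) return(list(s = 0, var_s = 0, z = 0, p = 1))
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  list(s = s, var_s = var_s, z = z, p = 2 * pnorm(-abs(z)))
}

# Independent direct-formula Gi* oracle: per-pixel loop over the 3x3
# neighbourhood, global stats over all valid pixels.
gi_bruteforce <- function(vals) {
  nr <- nrow(vals); nc <- ncol(vals)
  v <- vals[!is.na(vals)]
  n <- length(v)
  xbar <- mean(v)
  s <- sqrt(sum((v - xbar)^2) / n)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) {
    for (c in 1:nc) {
      if (is.na(vals[r, c])) next
      nb <- c()
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              !is.na(vals[rr, cc])) {
            nb <- c(nb, vals[rr, cc])
          }
        }
      }
      wi <- length(nb)
      if (n * wi - wi^2 <= 0) { out[r, c] <- 0; next }
      out[r, c] <- (sum(nb) - xbar * wi) /
        (s * sqrt((n * wi - wi^2) / (n - 1)))
    }
  }
  out
}

# A compact synthetic scene reused by several test files.
small_scene <- function(seed = 42, noise_sd = 1, n = 48, years = 1984:2012) {
  rec <- scene_recipe(
    n_rows = n, n_cols = n, years = years, seed = seed, noise_sd = noise_sd,
    clusters = tibble::tibble(row = c(round(n / 4), round(3 * n / 4)),
                              col = c(round(n / 4), round(3 * n / 4)),
                              radius = c(round(n / 8), round(n / 8)),
                              trend = c(-0.5, 0.5)))
  make_scene(rec)
}

# Telemetry fixture: one animal, regular interval, fixed location drift.
toy_track <- function(animal = "A1", start = "2008-01-01 00:00:00",
                      n = 10, dt_hours = 5, lon0 = -115, lat0 = 65,
                      dlat = 0, herd = "west", sex = "cow") {
  ts <- as.POSIXct(start, tz = "UTC") + (0:(n - 1)) * dt_hours * 3600
  tibble::tibble(animal_id = animal, herd = herd, sex = sex, timestamp = ts,
                 lon = lon0, lat = lat0 + (0:(n - 1)) * dlat)
}
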