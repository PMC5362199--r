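range_square <- function(id, x0, x1, y0, y1) {
  tibble::tibble(herd_id = id, x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# A 2x2 trend raster with known classes, for counting checks.
tiny_classed <- function() {
  g <- grid_spec(2, 2, 30, crs_id = "EPSG:3978")
  years <- 1990:2004
  lv <- lapply(years, function(y) {
    scalar_raster(g, matrix(c(10 + 0.5 * (y - 1990), 20 + 0.5 * (y - 1990),
                              30 - 0.5 * (y - 1990), 7), 2, 2))
  })
  names(lv) <- years
  trend_raster(lv, min_years = 10)  # classes: inc, inc, dec, no_change
}

test_that("zonal percentages are straight counting over classified pixels", {
  tr <- tiny_classed()
  mask <- all_true_mask(tr$grid)
  ranges <- herd_ranges(range_square("all", -10, 100, -10, 100))
  z <- zonal_class_percentages(tr, mask, ranges)
  expect_equal(z$pct[z$class == "increasing"], 50)
  expect_equal(z$pct[z$class == "decreasing"], 25)
  expect_equal(z$pct[z$class == "no_change"], 25)
  expect_equal(sum(z$n_pixels), 4)

  far <- herd_ranges(range_square("far", 1e5, 2e5, 1e5, 2e5))
  expect_error(zonal_class_percentages(tr, mask, far), "empty-zone")

  # hotspot rasters summarise through the same interface
  set.seed(30)
  h <- gi_star(toy_raster(matrix(rnorm(400), 20, 20)))
  zh <- zonal_class_percentages(h, all_true_mask(h$grid),
                                herd_ranges(range_square("a", -1, 1e4, -1, 1e4)))
  expect_setequal(zh$class,
                  c("positive_cluster", "negative_cluster", "no_cluster"))
  expect_equal(sum(zh$pct), 100)
})

test_that("zonal percentages sum to 100 and conserve pixel counts on scenes", {
  sc <- small_scene(seed = 31, n = 40)
  lv <- lve_stack(sc$stack, sc$mask, sc$recipe$params)
  tr <- trend_raster(lv)
  z <- zonal_class_percentages(tr, sc$mask, sc$ranges)
  sums <- tapply(z$pct, z$herd_id, sum)
  expect_true(all(abs(sums - 100) <= 0.01))
  # counts equal the class partition restricted to each herd polygon
  cc <- cell_centers(tr$grid)
  cls <- tr$change_class[cbind(cc$row, cc$col)]
  eligible <- sc$mask$is_lichen[cbind(cc$row, cc$col)] & !is.na(cls)
  for (h in unique(z$herd_id)) {
    poly <- sc$ranges[sc$ranges$herd_id == h, ]
    inside <- mgcv::in.out(rbind(cbind(poly$x, poly$y),
                                 cbind(poly$x[1], poly$y[1])),
                           cbind(cc$x, cc$y))
    for (cl in unique(z$class)) {
      expect_equal(z$n_pixels[z$herd_id == h & z$class == cl],
                   sum(inside & eligible & cls == cl))
    }
  }
})

test_that("planted class mixes are recovered in the herd summaries", {
  sc <- small_scene(seed = 32, n = 48)
  lv <- lve_stack(sc$stack, sc$mask, sc$recipe$params)
  z <- zonal_class_percentages(trend_raster(lv), sc$mask, sc$ranges)
  west_dec <- z$pct[z$herd_id == "west" & z$class == "decreasing"]
  west_inc <- z$pct[z$herd_id == "west" & z$class == "increasing"]
  east_dec <- z$pct[z$herd_id == "east" & z$class == "decreasing"]
  east_inc <- z$pct[z$herd_id == "east" & z$class == "increasing"]
  expect_gt(west_dec, east_dec)  # negative clusters planted in the west
  expect_gt(east_inc, west_inc)  # positive clusters planted in the east
})

test_that("stratified sampling allocates by stratum and is deterministic", {
  set.seed(33)
  g <- grid_spec(20, 20, 30, crs_id = "EPSG:3978")
  slopes <- scalar_raster(g, matrix(rnorm(400), 20, 20))
  ranges <- herd_ranges(range_square("h", -1, 601, -1, 601), crs_id = "EPSG:3978")
  s1 <- stratified_sample(slopes, ranges, n = 100, seed = 9)
  s2 <- stratified_sample(slopes, ranges, n = 100, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_false(any(duplicated(s1[, c("row", "col")])))
  expect_equal(s1$slope, slopes$values[cbind(s1$row, s1$col)])

  # n = 4 over a uniform square: one draw per quadrant
  s4 <- stratified_sample(slopes, ranges, n = 4, seed = 2)
  qx <- s4$x > 300; qy <- s4$y > 300
  expect_equal(sort(paste(qx, qy)),
               sort(c("TRUE TRUE", "TRUE FALSE", "FALSE TRUE", "FALSE FALSE")))

  expect_error(stratified_sample(slopes, ranges, n = 401, seed = 1),
               "insufficient-data")
})

test_that("largest-remainder allocation is proportional and exact", {
  # counting oracle: quotas 4 * c(50,30,20)/100 = (2, 1.2, 0.8)
  a <- lichentrend:::largest_remainder(4 * c(50, 30, 20) / 100, 4,
                                       cap = c(50, 30, 20))
  expect_equal(sum(a), 4)
  expect_equal(a, c(2, 1, 1))
  # caps bind and overflow is redistributed
  b <- lichentrend:::largest_remainder(c(3.5, 3.5, 3), 10, cap = c(2, 10, 10))
  expect_equal(sum(b), 10)
  expect_lte(b[1], 2)
})

test_that("herd ranges round-trip through GeoJSON", {
  r <- herd_ranges(dplyr::bind_rows(range_square("west", 0, 100, 0, 100),
                                    range_square("east", 120, 220, 0, 100)),
                   crs_id = "EPSG:3978")
  path <- file.path(withr::local_tempdir(), "herds.geojson")
  write_herd_ranges(r, path)
  back <- read_herd_ranges(path)
  expect_equal(as.data.frame(back), as.data.frame(r))
  expect_identical(attr(back, "crs_id"), "EPSG:3978")
})

test_that("GLS with independent errors reproduces ordinary group means exactly", {
  d <- simulate_herd_samples(means = c(0.1, -0.2, 0.05), seed = 5)
  fit <- gls_herd_model(d, correlation = "none")
  ols <- tapply(d$slope, d$herd_id, mean)
  expect_equal(fit$group_means$mean_slope,
               as.numeric(ols[fit$group_means$herd_id]), tolerance = 1e-10)
  expect_true(is.na(fit$lr_statistic))
})

test_that("the spatial GLS detects planted mean differences and correlation", {
  d <- simulate_herd_samples(means = c(0.3, 0, -0.3), grid_per_herd = 7,
                             range_m = 1500, nugget = 0.3, seed = 11)
  fit <- gls_herd_model(d, correlation = "gaussian")
  expect_gte(fit$lr_statistic, 0)
  expect_lt(fit$f_p, 0.05)
  # group means within 2 SE of truth
  td <- tidy(fit)
  se_scale <- max(td$std_error) * 2.5
  got <- fit$group_means$mean_slope
  expect_true(all(abs(got - c(0.3, 0, -0.3)) < pmax(2 * se_scale, 0.25)))
  expect_true(fit$correlation_range > 0)
  g <- glance(fit)
  expect_gt(g$logLik_spatial, g$logLik_independent)
})

test_that("Tukey HSD reduces to the unadjusted test for two groups", {
  d <- simulate_herd_samples(means = c(0, 0.15), grid_per_herd = 5, seed = 7)
  fit <- gls_herd_model(d, correlation = "none")
  tk <- tukey_pairwise(fit)
  expect_equal(nrow(tk), 1)
  # k = 2: studentized-range adjustment is the identity
  expect_equal(tk$adj_p_value, fit$f_p, tolerance = 1e-8)
})

test_that("identical per-herd data yield adjusted p of 1", {
  vals <- rep(rnorm(10, 0, 0.1), 3)
  d <- simulate_herd_samples(means = c(0, 0, 0), grid_per_herd = 4, seed = 3)
  d$slope <- rep(rnorm(16, 0, 0.1), 3)  # same values in every herd
  fit <- gls_herd_model(d, correlation = "none")
  tk <- tukey_pairwise(fit)
  expect_true(all(tk$adj_p_value >= 0.999))
  expect_true(all(abs(tk$estimate) < 1e-12))
})

test_that("Tukey adjusted p matches the studentized-range distribution directly", {
  d <- simulate_herd_samples(means = c(0.2, 0, -0.1), grid_per_herd = 6,
                             seed = 19)
  fit <- gls_herd_model(d, correlation = "none")
  tk <- tukey_pairwise(fit)
  # independent oracle: p = P(q_{k,df} > |t| * sqrt(2)) from the t ratios
  k <- 3; df <- nrow(d) - k
  oracle <- ptukey(abs(tk$t_ratio) * sqrt(2), k, df, lower.tail = FALSE)
  expect_equal(tk$adj_p_value, oracle, tolerance = 0.01)
})

test_that("residual semivariograms rise with distance under spatial correlation", {
  d <- simulate_herd_samples(means = c(0, 0, 0), range_m = 3000, nugget = 0.2,
                             seed = 23)
  sv <- residual_semivariogram(d$slope, d$x, d$y, n_bins = 10)
  expect_true(all(c("distance", "gamma", "n_pairs") %in% names(sv)))
  expect_gt(mean(sv$gamma[sv$distance > 5000]),
            mean(sv$gamma[sv$distance < 1500]))
})
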