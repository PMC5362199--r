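test_that("index inversion reproduces targets and band triples solve exactly", {
  # algebraic solve-and-check oracle over a grid of index targets
  grid <- seq(-0.89, 0.89, length.out = 12)
  for (a in grid) {
    b <- rev(grid)[match(a, grid)]
    bands <- lichentrend:::bands_from_indices(a, b)
    expect_true(all(unlist(bands) > 0 & unlist(bands) <= 1))
    expect_equal(ndli(bands$swir1, bands$green), a, tolerance = 1e-9)
    expect_equal(ndmi(bands$nir, bands$swir1), b, tolerance = 1e-9)
  }
  # LVE-level inversion: score(invert(L)) == L for any direction
  p <- lve_params(center_mode = "fixed", rho = 0.4)
  set.seed(60)
  L <- runif(50, 1, 99)
  th <- runif(50, 0, 2 * pi)
  idx <- lichentrend:::invert_lve(L, th, p)
  expect_equal(lve_score(idx$ndli, idx$ndmi, p), L, tolerance = 1e-9)
})

test_that("a noise-free scene yields exactly the planted slopes", {
  rec <- scene_recipe(n_rows = 24, n_cols = 24, years = 2000:2010,
                      noise_sd = 0, seed = 61,
                      clusters = tibble::tibble(row = 8, col = 8, radius = 5,
                                                trend = 0.5))
  sc <- make_scene(rec)
  lv <- lve_stack(sc$stack, sc$mask, rec$params)
  tr <- trend_raster(lv, min_years = 5)
  ok <- !is.na(tr$slope)
  expect_true(any(ok))
  expect_equal(tr$slope[ok], sc$truth$slope$values[ok], tolerance = 1e-6)
  inside <- ok & sc$truth$cluster == 1L
  expect_true(all(tr$change_class[inside] == "increasing"))
})

test_that("recipes validate cluster placement and amplitude headroom", {
  expect_error(scene_recipe(n_rows = 20, n_cols = 20,
                            clusters = tibble::tibble(row = 2, col = 10,
                                                      radius = 5, trend = 0.5)),
               "recipe error")
  expect_error(scene_recipe(baseline_lve = 95), "amplitude")
  expect_error(scene_recipe(params = lve_params(center_mode = "scene_mean")),
               "fixed")
  # lichen_fraction 0 leaves nothing to analyse downstream
  sc0 <- make_scene(scene_recipe(n_rows = 8, n_cols = 8, lichen_fraction = 0,
                                 years = 2000:2005, seed = 1,
                                 clusters = tibble::tibble(row = 4, col = 4,
                                                           radius = 2,
                                                           trend = 0.1)))
  expect_error(lve_stack(sc0$stack, sc0$mask,
                         lve_params(amplitude = 100)), "empty-domain")
})

test_that("scene generation is deterministic in the recipe seed", {
  rec <- scene_recipe(n_rows = 16, n_cols = 16, years = 2000:2004, seed = 62)
  s1 <- make_scene(rec)
  s2 <- make_scene(rec)
  expect_identical(s1$stack$values, s2$stack$values)
  expect_identical(s1$mask$is_lichen, s2$mask$is_lichen)
  s3 <- make_scene(scene_recipe(n_rows = 16, n_cols = 16, years = 2000:2004,
                                seed = 63))
  expect_false(identical(s1$stack$values, s3$stack$values))
})

test_that("nodata holes invalidate whole year-cells through the pipeline", {
  rec <- scene_recipe(n_rows = 16, n_cols = 16, years = 2000:2009,
                      nodata_fraction = 0.05, seed = 64)
  sc <- make_scene(rec)
  expect_gt(sum(is.na(sc$stack$values)), 0)
  lv <- lve_stack(sc$stack, sc$mask, rec$params)
  y1 <- matrix(sc$stack$values[1, 1, , ], 16, 16)
  expect_true(all(is.na(lv[[1]]$values[is.na(y1)])))
})

test_that("tracks are byte-identical for the same seed and shift otherwise", {
  sc <- make_scene(scene_recipe(n_rows = 24, n_cols = 24, years = 2008:2009,
                                seed = 65))
  lv <- lve_stack(sc$stack, sc$mask, sc$recipe$params)
  rec <- track_recipe(n_animals = 2, years = 2008:2008, seed = 66)
  t1 <- make_tracks(rec, lv)
  t2 <- make_tracks(rec, lv)
  f1 <- file.path(withr::local_tempdir(), "t1.csv")
  f2 <- file.path(withr::local_tempdir(), "t2.csv")
  utils::write.csv(t1, f1, row.names = FALSE)
  utils::write.csv(t2, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  t3 <- make_tracks(track_recipe(n_animals = 2, years = 2008:2008, seed = 67), lv)
  expect_false(identical(t1$lon, t3$lon))
  # 5 h and 8 h collars alternate
  expect_setequal(
    round(tapply(as.numeric(t1$timestamp), t1$animal_id,
                 function(z) min(diff(z)))) / 3600, c(5, 8))
})

test_that("a flat response produces the planted mean velocity (LLN check)", {
  # 500 m cells: a 16 km domain, large relative to ~2 km steps, so boundary
  # reflections are rare and do not distort the mean
  sc <- make_scene(scene_recipe(n_rows = 32, n_cols = 32, cell_size = 500,
                                years = 2008:2009, seed = 68))
  lv <- lve_stack(sc$stack, sc$mask, sc$recipe$params)
  flat <- season_response("flat", base = 240)
  rec <- track_recipe(n_animals = 6, years = 2008:2009,
                      responses = list(spring = flat, summer = flat,
                                       fall = flat, winter = flat),
                      seed = 69)
  fx <- make_tracks(rec, lv)
  st <- step_velocities(fx)
  expect_gt(nrow(st), 10000)
  # steps starting > 2 km inside the boundary cannot have been reflected,
  # so their telemetry distance equals the drawn step length exactly
  proj <- parse_local_projection(lv[[1]]$grid$crs_id)
  xy <- proj$forward(st$lon, st$lat)
  interior <- abs(xy[, 1]) < 6000 & abs(xy[, 2]) < 6000
  expect_gt(sum(interior), 5000)
  expect_lt(abs(mean(st$velocity[interior]) - 240) / 240, 0.02)
})

test_that("a planted velocity breakpoint appears in binned track velocities", {
  # wide baseline gradient so steps sample a wide LVE range
  sc <- make_scene(scene_recipe(n_rows = 48, n_cols = 48, cell_size = 500,
                                years = 2008:2009,
                                baseline_lve = c(5, 60), noise_sd = 0.5,
                                seed = 70))
  lv <- lve_stack(sc$stack, sc$mask, sc$recipe$params)
  resp <- season_response("threshold_decline", base = 300, rate = 10,
                          threshold = 30, floor = 40)
  rec <- track_recipe(n_animals = 8, years = 2008:2009,
                      responses = list(spring = resp, summer = resp,
                                       fall = resp, winter = resp),
                      turn_sd = 2.5,  # strong mixing over the gradient
                      seed = 71)
  st <- extract_lve_at_fixes(step_velocities(make_tracks(rec, lv)), lv)
  st <- st[!is.na(st$lve_at_start), ]
  bins <- seq(5, 60, by = 5)
  bm <- tapply(st$velocity, cut(st$lve_at_start, bins), mean)
  centers <- bins[-1] - 2.5
  # binned-mean oracle: fit flat-then-linear-decline models at every
  # candidate breakpoint; the best-fitting breakpoint is the planted one
  # (LVE 30) within one bin width
  sse <- sapply(centers[3:(length(centers) - 2)], function(b) {
    below <- centers < b
    sum((bm[below] - mean(bm[below]))^2) +
      sum(resid(lm(bm[!below] ~ centers[!below]))^2)
  })
  b_hat <- centers[3:(length(centers) - 2)][which.min(sse)]
  expect_lte(abs(b_hat - 30), 5)
  # below the threshold the response is flat
  below <- bm[centers < 25]
  expect_lt(max(below) - min(below), 0.15 * 300)
})

test_that("the direct step-table simulator honours its generative model", {
  d1 <- simulate_step_table(400, 4, season_response("flat", base = 200),
                            seed = 72)
  d2 <- simulate_step_table(400, 4, season_response("flat", base = 200),
                            seed = 72)
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1$velocity) - mean(d1$mu_true)) / 200, 0.05)
  dd <- simulate_step_table(2000, 5,
                            season_response("linear_decline", base = 300,
                                            rate = 4),
                            animal_sd = 0, seed = 73)
  lo <- dd$velocity[dd$lve_at_start < 20]
  hi <- dd$velocity[dd$lve_at_start > 40]
  expect_gt(mean(lo), mean(hi) + 50)
})
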