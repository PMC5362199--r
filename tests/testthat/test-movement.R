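test_that("the QC filter applies the complete-year, fixes-per-day rule", {
  # exactly 3 fixes/day for 365 consecutive days -> retained
  good <- toy_track("good", n = 3 * 365, dt_hours = 8)
  # one thin day (2 fixes) in the middle of an otherwise complete year
  thin <- toy_track("thin", n = 3 * 365, dt_hours = 8)
  drop_day <- as.Date("2008-06-01")
  thin <- thin[!(as.Date(thin$timestamp) == drop_day &
                   format(thin$timestamp, "%H") == "08"), ]
  # long run but short of a year
  short <- toy_track("short", n = 3 * 200, dt_hours = 8)
  # five-animal fixture with known pass/fail
  sparse <- toy_track("sparse", n = 100, dt_hours = 24)
  fast <- toy_track("fast", n = 5 * 366, dt_hours = 4.8)
  fixes <- dplyr::bind_rows(good, thin, short, sparse, fast)
  kept <- qc_filter(fixes)
  expect_setequal(unique(kept$animal_id), c("good", "fast"))
  dropped <- attr(kept, "dropped")
  expect_setequal(dropped$animal_id, c("thin", "short", "sparse"))
  expect_match(dropped$reason[dropped$animal_id == "sparse"], ">= 3 fixes")
  # idempotent
  again <- qc_filter(kept)
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)
  expect_equal(nrow(attr(again, "dropped")), 0)
})

test_that("step velocities follow haversine distance over elapsed time", {
  # two fixes 1000 m apart (meridian arc), 5 h apart -> 200 m/h
  dlat <- 1000 / 6371000 * 180 / pi
  fx <- toy_track("a", n = 2, dt_hours = 5, dlat = dlat)
  st <- step_velocities(fx)
  expect_equal(st$distance, 1000, tolerance = 1e-9)
  expect_equal(st$velocity, 200, tolerance = 1e-9)
  expect_equal(st$dt, 5)

  # identical coordinates -> zero velocity
  st0 <- step_velocities(toy_track("b", n = 3, dt_hours = 5))
  expect_equal(st0$velocity, c(0, 0))

  # one-degree arc of longitude at the equator, closed form pi*R/180
  eq <- tibble::tibble(animal_id = "e", herd = "h", sex = "cow",
                       timestamp = as.POSIXct("2008-01-01", tz = "UTC") +
                         c(0, 5) * 3600,
                       lon = c(0, 1), lat = c(0, 0))
  ste <- step_velocities(eq)
  expect_equal(ste$distance, pi * 6371000 / 180, tolerance = 1e-4)
  expect_equal(ste$distance, 111194.9, tolerance = 1e-6)

  # steps beyond the maximum time step are excluded
  gap <- toy_track("g", n = 5, dt_hours = 5)
  gap$timestamp[4:5] <- gap$timestamp[4:5] + 20 * 3600
  expect_equal(nrow(step_velocities(gap)), 3)

  # duplicate timestamps are skipped with a warning
  dup <- toy_track("d", n = 4, dt_hours = 5)
  dup$timestamp <- dup$timestamp[1] + c(0, 5, 5, 10) * 3600
  expect_warning(std <- step_velocities(dup), "non-increasing")
  expect_equal(nrow(std), 2)
})

test_that("velocity is invariant under track reversal", {
  set.seed(40)
  fx <- toy_track("r", n = 20, dt_hours = 5, dlat = 0.01)
  fx$lon <- fx$lon + cumsum(rnorm(20, 0, 0.01))
  st <- step_velocities(fx)
  rev_fx <- fx
  rev_fx$lon <- rev(fx$lon); rev_fx$lat <- rev(fx$lat)
  st_rev <- step_velocities(rev_fx)
  expect_equal(rev(st_rev$velocity), st$velocity)
})

test_that("season assignment covers every day of a leap year exactly once", {
  cal <- season_calendar()
  expect_identical(assign_season(as.POSIXct("2008-07-15", tz = "UTC"), cal),
                   "summer")
  # inclusive starts at every boundary
  expect_identical(assign_season(as.POSIXct("2008-04-16", tz = "UTC"), cal),
                   "spring")
  expect_identical(assign_season(as.POSIXct("2008-04-15", tz = "UTC"), cal),
                   "winter")
  expect_identical(assign_season(as.POSIXct("2008-12-01", tz = "UTC"), cal),
                   "winter")
  days <- seq(as.Date("2008-01-01"), as.Date("2008-12-31"), by = "day")
  expect_equal(length(days), 366)
  seas <- assign_season(as.POSIXct(paste(days, "12:00:00"), tz = "UTC"), cal)
  expect_true(all(seas %in% c("spring", "summer", "fall", "winter")))
  expect_equal(sum(seas == "spring"), as.numeric(as.Date("2008-06-07") -
                                                   as.Date("2008-04-16")) + 1)
  # a wrapped window spanning the new year also validates
  expect_error(season_calendar(spring = c("04-16", "06-07"),
                               summer = c("06-08", "09-07"),
                               fall = c("09-08", "11-29"),   # gap on Nov 30
                               winter = c("12-01", "04-15")),
               "exactly once")
})

test_that("the 95% MCP drops the farthest fixes before taking the hull", {
  proj <- local_projection(-115, 65)
  # 4 corners + center, full retention -> the square
  sq <- proj$inverse(c(0, 1000, 1000, 0, 500), c(0, 0, 1000, 1000, 500))
  fx <- tibble::tibble(lon = sq[, 1], lat = sq[, 2])
  r100 <- mcp_range(fx, "sq", proj, percent = 100)
  expect_equal(sort(r100$x), sort(c(0, 0, 1000, 1000)), tolerance = 1e-6)

  # 100 clustered points + 5 distant outliers, 95% -> outliers excluded
  set.seed(41)
  xy <- cbind(rnorm(100, 0, 50), rnorm(100, 0, 50))
  out <- cbind(c(5e4, -5e4, 5e4, -5e4, 6e4), c(5e4, 5e4, -5e4, -5e4, 0))
  ll <- proj$inverse(c(xy[, 1], out[, 1]), c(xy[, 2], out[, 2]))
  fx2 <- tibble::tibble(lon = ll[, 1], lat = ll[, 2])
  r95 <- mcp_range(fx2, "c", proj, percent = 95)
  expect_true(all(abs(r95$x) < 1e4) && all(abs(r95$y) < 1e4))

  # hull area is monotone non-decreasing in the retention percentage
  areas <- sapply(c(50, 70, 90, 100), function(p) {
    ring <- mcp_range(fx2, "c", proj, percent = p)
    lichentrend:::polygon_area(cbind(ring$x, ring$y))
  })
  expect_true(all(diff(areas) >= 0))

  expect_error(mcp_range(fx2[1:3, ], "c", proj), "insufficient-data")
  expect_warning(
    mcp_range(tibble::tibble(lon = -115 + (0:5) * 0.001, lat = 65), "l", proj),
    "degenerate")
})

test_that("LVE extraction reads the right cell, year and validity", {
  proj <- local_projection(-115, 65)
  g <- grid_spec(4, 4, 30, origin_x = -60, origin_y = 60,
                 crs_id = proj$crs_id)
  m1 <- matrix(as.numeric(1:16), 4, 4); m1[2, 2] <- NA
  m2 <- m1 + 100
  lv <- list("2008" = scalar_raster(g, m1), "2009" = scalar_raster(g, m2))
  # construct fixes at known cell centers (row 1 col 1; row 2 col 2; outside)
  cc <- cell_centers(g)
  pick <- function(r, c) cc[cc$row == r & cc$col == c, ]
  pts <- rbind(pick(1, 1), pick(3, 4), pick(2, 2))
  ll <- proj$inverse(c(pts$x, 1e6), c(pts$y, 0))
  steps <- tibble::tibble(
    year = c(2008L, 2009L, 2008L, 2008L),
    lon = ll[, 1], lat = ll[, 2])
  got <- extract_lve_at_fixes(steps, lv, proj)
  expect_equal(got$lve_at_start[1], m1[1, 1])
  expect_equal(got$lve_at_start[2], m2[3, 4])
  expect_true(is.na(got$lve_at_start[3]))    # invalid (non-lichen) cell
  expect_true(is.na(got$lve_at_start[4]))    # outside the extent
  # missing year -> missing value
  got2 <- extract_lve_at_fixes(dplyr::mutate(steps[1, ], year = 1999L), lv, proj)
  expect_true(is.na(got2$lve_at_start))
})

test_that("haversine and the local tangent plane agree at arctic scales", {
  proj <- local_projection(-115, 65)
  set.seed(42)
  # steps up to 10 km across an extent like the analysis scenes (a few km
  # around the reference point; east-west distortion grows with the
  # latitude offset, so the agreement is a near-reference property)
  for (k in 1:20) {
    x <- runif(2, -5000, 5000)
    y <- runif(2, -1250, 1250)
    len <- sqrt(diff(x)^2 + diff(y)^2)
    ll <- proj$inverse(x, y)
    hav <- geosphere::distHaversine(ll[1, ], ll[2, ], r = 6371000)
    expect_equal(hav, len, tolerance = 1e-3)  # < 0.1% relative error
  }
  # projection round-trips
  ll <- proj$inverse(123.4, -567.8)
  xy <- proj$forward(ll[1], ll[2])
  expect_equal(as.numeric(xy), c(123.4, -567.8), tolerance = 1e-6)
  expect_equal(parse_local_projection(proj$crs_id)$lat0, 65)
})

test_that("telemetry CSV reading validates columns and coordinates", {
  dir <- withr::local_tempdir()
  fx <- toy_track("a", n = 5)
  path <- file.path(dir, "tele.csv")
  utils::write.csv(fx, path, row.names = FALSE)
  back <- read_telemetry(path)
  expect_equal(back$lon, fx$lon)
  expect_s3_class(back$timestamp, "POSIXct")
  utils::write.csv(fx[, -1], path, row.names = FALSE)
  expect_error(read_telemetry(path), "missing column")
})
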