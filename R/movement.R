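#' Local tangent-plane projection
#'
#' A minimal equirectangular projection centered on a reference point: metres
#' east/north on a sphere of radius 6,371,000 m. At arctic latitudes and the
#' step lengths of caribou telemetry (a few km) it agrees with great-circle
#' geometry to well under 0.1%, which is the accuracy the raster lookups
#' need. The object carries forward and inverse transforms and a CRS id
#' that encodes its parameters.
#'
#' @param lon0,lat0 Reference longitude/latitude in degrees.
#' @param radius Sphere radius in metres.
#' @return An object of class `local_projection` with functions
#'   `$forward(lon, lat)` and `$inverse(x, y)` (both return two-column
#'   matrices) and `$crs_id`.
#' @export
local_projection <- function(lon0, lat0, radius = 6371000) {
  k <- pi / 180
  cos0 <- cos(lat0 * k)
  structure(
    list(
      lon0 = lon0, lat0 = lat0, radius = radius,
      crs_id = sprintf("LOCAL_ER(%.10g,%.10g,%.10g)", lon0, lat0, radius),
      forward = function(lon, lat) {
        cbind(x = radius * cos0 * (lon - lon0) * k,
              y = radius * (lat - lat0) * k)
      },
      inverse = function(x, y) {
        cbind(lon = lon0 + x / (radius * cos0) / k,
              lat = lat0 + y / radius / k)
      }
    ),
    class = "local_projection"
  )
}

#' Parse a local-projection CRS id back into a projection
#'
#' @param crs_id A string produced by [local_projection()].
#' @return A `local_projection`.
#' @export
parse_local_projection <- function(crs_id) {
  m <- regmatches(crs_id,
                  regexec("^LOCAL_ER\\(([^,]+),([^,]+),([^)]+)\\)$", crs_id))[[1]]
  if (length(m) != 4) {
    stop("'", crs_id, "' is not a local_projection CRS id", call. = FALSE)
  }
  local_projection(as.numeric(m[2]), as.numeric(m[3]), as.numeric(m[4]))
}

#' Read GPS telemetry from delimited text
#'
#' Expected columns: `animal_id`, `herd`, `sex`, `timestamp` (ISO-8601,
#' interpreted as UTC), `lon`, `lat`. Fixes are ordered by animal and time;
#' coordinates are validated.
#'
#' @param path CSV file.
#' @return A tibble of fixes, one row per GPS point.
#' @export
read_telemetry <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "herd", "sex", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("I/O error: telemetry file missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- tibble::as_tibble(d)
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
  if (anyNA(d$timestamp)) {
    stop("I/O error: unparseable timestamps in telemetry", call. = FALSE)
  }
  if (any(abs(d$lat) > 90) || any(abs(d$lon) > 180)) {
    stop("telemetry coordinates outside [-180,180] x [-90,90]", call. = FALSE)
  }
  dplyr::arrange(d, .data$animal_id, .data$timestamp)
}

#' Quality-control filter for telemetry
#'
#' Keeps animals with at least one run of `min_days` consecutive calendar
#' days on each of which the animal has at least `min_fixes_per_day` fixes —
#' the "complete year of tracking at three or more fixes per day" inclusion
#' rule. Dropped animals are recorded (with the reason) in the `"dropped"`
#' attribute of the result. Idempotent.
#'
#' @param fixes A telemetry tibble (see [read_telemetry()]).
#' @param min_fixes_per_day Minimum fixes per qualifying day (default 3).
#' @param min_days Length of the required consecutive-day run (default 365).
#' @return The fixes of retained animals, with attribute `dropped` (tibble
#'   `animal_id`, `reason`).
#' @export
qc_filter <- function(fixes, min_fixes_per_day = 3, min_days = 365) {
  fixes <- dplyr::arrange(tibble::as_tibble(fixes),
                          .data$animal_id, .data$timestamp)
  per_animal <- split(fixes, fixes$animal_id)
  verdict <- purrr::map_chr(per_animal, function(a) {
    days <- as.Date(a$timestamp, tz = "UTC")
    tab <- table(days)
    good <- as.Date(names(tab)[tab >= min_fixes_per_day])
    if (!length(good)) return(sprintf("no day with >= %d fixes", min_fixes_per_day))
    runs <- split(good, cumsum(c(1, diff(good) != 1)))
    if (max(lengths(runs)) >= min_days) "ok"
    else sprintf("longest qualifying run %d < %d days",
                 max(lengths(runs)), min_days)
  })
  keep <- names(verdict)[verdict == "ok"]
  out <- fixes[fixes$animal_id %in% keep, ]
  attr(out, "dropped") <- tibble::tibble(
    animal_id = names(verdict)[verdict != "ok"],
    reason = unname(verdict[verdict != "ok"])
  )
  out
}

#' Default season calendar
#'
#' Month-day windows partitioning the year into the four seasons the
#' movement models are stratified by. The defaults bracket the conventional
#' caribou year (calving within spring, rut within fall, snow season as
#' winter) and are fully configurable: spring Apr 16 - Jun 7, summer
#' Jun 8 - Sep 7, fall Sep 8 - Nov 30, winter Dec 1 - Apr 15 (wrapping the
#' new year). Every possible month-day (Feb 29 included) belongs to exactly
#' one season.
#'
#' @param spring,summer,fall,winter Two-element character vectors of
#'   inclusive `"MM-DD"` start/end.
#' @return An object of class `season_calendar`.
#' @export
season_calendar <- function(spring = c("04-16", "06-07"),
                            summer = c("06-08", "09-07"),
                            fall = c("09-08", "11-30"),
                            winter = c("12-01", "04-15")) {
  cal <- tibble::tibble(
    season = c("spring", "summer", "fall", "winter"),
    start = c(spring[1], summer[1], fall[1], winter[1]),
    end = c(spring[2], summer[2], fall[2], winter[2])
  )
  md_num <- function(md) {
    p <- strsplit(md, "-")
    vapply(p, function(q) as.integer(q[1]) * 100L + as.integer(q[2]), 1L)
  }
  cal$start_n <- md_num(cal$start)
  cal$end_n <- md_num(cal$end)
  obj <- structure(cal, class = c("season_calendar", class(cal)))
  # validate: all 366 month-days covered exactly once
  days <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  hits <- vapply(as.integer(format(days, "%m")) * 100L +
                   as.integer(format(days, "%d")),
                 function(n) sum(season_of_md(obj, n) == obj$season),
                 1L)
  if (any(hits != 1)) {
    stop("season_calendar: windows must cover every month-day exactly once",
         call. = FALSE)
  }
  obj
}

season_of_md <- function(cal, md_n) {
  wrap <- cal$start_n > cal$end_n
  hit <- (!wrap & md_n >= cal$start_n & md_n <= cal$end_n) |
    (wrap & (md_n >= cal$start_n | md_n <= cal$end_n))
  cal$season[hit]
}

#' Assign a season to timestamps
#'
#' Month-day lookup in a [season_calendar()]; window starts are inclusive.
#'
#' @param ts POSIXct (or Date) timestamps.
#' @param cal A [season_calendar()].
#' @return Character vector of seasons.
#' @export
assign_season <- function(ts, cal = season_calendar()) {
  stopifnot(inherits(cal, "season_calendar"))
  md_n <- as.integer(format(ts, "%m", tz = "UTC")) * 100L +
    as.integer(format(ts, "%d", tz = "UTC"))
  vapply(md_n, function(n) season_of_md(cal, n), "")
}

#' Per-step velocities from telemetry
#'
#' Consecutive-fix great-circle distances (haversine on a 6,371,000 m
#' sphere) divided by elapsed hours. Velocity rather than step length is
#' the movement metric because animals are tracked at two different fix
#' intervals (5 h and 8 h). Steps longer than `max_dt_hours` (missed fixes)
#' are excluded; duplicate timestamps are skipped with a warning. The season
#' and year of a step come from its start fix.
#'
#' @param fixes A telemetry tibble (post-[qc_filter()]).
#' @param max_dt_hours Maximum allowed time step in hours; the default 9
#'   is the nominal 8 h interval plus 1 h tolerance.
#' @param cal A [season_calendar()].
#' @return A step tibble: `animal_id`, `herd`, `sex`, `start`, `end`, `dt`
#'   (h), `distance` (m), `velocity` (m/h), `season`, `year`, `lon`, `lat`
#'   (start fix).
#' @export
step_velocities <- function(fixes, max_dt_hours = 9, cal = season_calendar()) {
  fixes <- dplyr::arrange(tibble::as_tibble(fixes),
                          .data$animal_id, .data$timestamp)
  steps <- fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(
      end_ts = dplyr::lead(.data$timestamp),
      end_lon = dplyr::lead(.data$lon),
      end_lat = dplyr::lead(.data$lat)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$end_ts))
  if (!nrow(steps)) {
    stop("insufficient-data error: need at least 2 fixes per animal",
         call. = FALSE)
  }
  steps$dt <- as.numeric(difftime(steps$end_ts, steps$timestamp, units = "hours"))
  dup <- steps$dt <= 0
  if (any(dup)) {
    warning(sum(dup), " step(s) with non-increasing timestamps skipped")
    steps <- steps[!dup, ]
  }
  steps$distance <- geosphere::distHaversine(
    cbind(steps$lon, steps$lat), cbind(steps$end_lon, steps$end_lat),
    r = 6371000)
  steps$velocity <- steps$distance / steps$dt
  long <- steps$dt > max_dt_hours
  if (any(long)) steps <- steps[!long, ]
  tibble::tibble(
    animal_id = steps$animal_id, herd = steps$herd, sex = steps$sex,
    start = steps$timestamp, end = steps$end_ts,
    dt = steps$dt, distance = steps$distance, velocity = steps$velocity,
    season = assign_season(steps$timestamp, cal),
    year = as.integer(format(steps$timestamp, "%Y", tz = "UTC")),
    lon = steps$lon, lat = steps$lat
  )
}

#' Minimum convex polygon home range
#'
#' The 95% MCP: fixes are projected to the raster CRS, the `1 - percent/100`
#' fraction farthest from the arithmetic mean location is removed, and the
#' convex hull of the remainder is the range polygon.
#'
#' @param fixes Telemetry tibble for one herd (columns `lon`, `lat`).
#' @param herd_id Label for the resulting polygon.
#' @param proj A [local_projection()] mapping lon/lat to the raster CRS.
#' @param percent Percentage of fixes retained (default 95).
#' @return A [herd_ranges()] with one polygon. A degenerate (collinear)
#'   point set yields a zero-area hull with a warning.
#' @export
mcp_range <- function(fixes, herd_id, proj, percent = 95) {
  stopifnot(inherits(proj, "local_projection"), percent > 0, percent <= 100)
  if (nrow(fixes) < 5) {
    stop("insufficient-data error: MCP needs at least 5 fixes", call. = FALSE)
  }
  xy <- proj$forward(fixes$lon, fixes$lat)
  ctr <- colMeans(xy)
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  keep <- d <= stats::quantile(d, percent / 100, type = 1)
  xy <- xy[keep, , drop = FALSE]
  hull <- grDevices::chull(xy)
  ring <- xy[hull, , drop = FALSE]
  if (nrow(ring) < 3 || polygon_area(ring) == 0) {
    warning("mcp_range: degenerate (collinear) fixes, zero-area hull")
    if (nrow(ring) < 3) {
      # keep a representable (zero-area) triangle for downstream contracts
      ring <- rbind(ring[1, ], ring[nrow(ring), ],
                    (ring[1, ] + ring[nrow(ring), ]) / 2)
    }
  }
  herd_ranges(tibble::tibble(herd_id = herd_id, x = ring[, 1], y = ring[, 2]),
              crs_id = proj$crs_id)
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Attach LVE values to steps by year and location
#'
#' Projects each step's start fix into the raster CRS and reads the LVE of
#' the containing cell from that step's year. Steps in years without an LVE
#' raster, outside the raster extent, or on invalid (non-lichen) cells get
#' `NA`.
#'
#' @param steps A step tibble from [step_velocities()].
#' @param lve_by_year Named list of [scalar_raster()] (names = years).
#' @param proj A [local_projection()]; defaults to the one encoded in the
#'   rasters' CRS id.
#' @return `steps` with an added `lve_at_start` column.
#' @export
extract_lve_at_fixes <- function(steps, lve_by_year, proj = NULL) {
  steps <- tibble::as_tibble(steps)
  g <- lve_by_year[[1]]$grid
  if (is.null(proj)) proj <- parse_local_projection(g$crs_id)
  xy <- proj$forward(steps$lon, steps$lat)
  at <- cells_at(g, xy[, 1], xy[, 2])
  lve <- rep(NA_real_, nrow(steps))
  for (y in unique(steps$year)) {
    r <- lve_by_year[[as.character(y)]]
    if (is.null(r)) next
    sel <- which(steps$year == y & !is.na(at$row))
    if (length(sel)) lve[sel] <- r$values[cbind(at$row[sel], at$col[sel])]
  }
  steps$lve_at_start <- lve
  steps
}
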