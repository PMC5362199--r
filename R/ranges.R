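#' Herd range polygons
#'
#' A collection of planar polygons in the raster CRS, one (simple, hole-free)
#' polygon per herd. Stored as a tibble of vertices so ranges pipe cleanly
#' into dplyr/ggplot2.
#'
#' @param vertices A data frame with columns `herd_id`, `x`, `y`; rows in
#'   ring order per herd (closing vertex optional).
#' @param crs_id CRS identifier the coordinates live in.
#' @return An object of class `herd_ranges` (a tibble with attributes).
#' @export
herd_ranges <- function(vertices, crs_id = "LOCAL") {
  v <- tibble::as_tibble(vertices)
  stopifnot(all(c("herd_id", "x", "y") %in% names(v)))
  v <- dplyr::group_by(v, .data$herd_id)
  v <- dplyr::filter(v, !(dplyr::row_number() == dplyr::n() &
                            .data$x == dplyr::first(.data$x) &
                            .data$y == dplyr::first(.data$y)))
  v <- dplyr::ungroup(v)
  counts <- dplyr::count(v, .data$herd_id)
  if (any(counts$n < 3)) {
    stop("herd_ranges: each polygon needs at least 3 distinct vertices",
         call. = FALSE)
  }
  structure(v[, c("herd_id", "x", "y")],
            class = c("herd_ranges", class(tibble::tibble())),
            crs_id = crs_id)
}

#' @export
print.herd_ranges <- function(x, ...) {
  cat(sprintf("<herd_ranges> %d herd(s): %s [crs '%s']\n",
              length(unique(x$herd_id)),
              paste(unique(x$herd_id), collapse = ", "),
              attr(x, "crs_id")))
  NextMethod()
}

herd_ids <- function(ranges) unique(ranges$herd_id)

range_polygon <- function(ranges, herd) {
  v <- ranges[ranges$herd_id == herd, ]
  if (!nrow(v)) stop("no herd '", herd, "' in ranges", call. = FALSE)
  cbind(v$x, v$y)
}

# Point-in-polygon for one herd's polygon (mgcv's boundary routine).
points_in_range <- function(ranges, herd, x, y) {
  bnd <- range_polygon(ranges, herd)
  mgcv::in.out(rbind(bnd, bnd[1, ]), cbind(x, y))
}

#' Read herd ranges from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or single-ring MultiPolygon)
#' features carrying a `herd_id` property. Holes are not supported.
#'
#' @param path GeoJSON file.
#' @param crs_id CRS identifier of the coordinates (GeoJSON written by
#'   [write_herd_ranges()] records it in a top-level `crs_id` member).
#' @return A [herd_ranges()] object.
#' @export
read_herd_ranges <- function(path, crs_id = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(crs_id)) crs_id <- gj$crs_id %||% "LOCAL"
  feats <- gj$features
  if (is.null(feats)) stop("I/O error: '", path, "' is not a FeatureCollection",
                           call. = FALSE)
  rows <- purrr::map_dfr(feats, function(f) {
    id <- f$properties$herd_id
    if (is.null(id)) stop("I/O error: feature without herd_id property",
                          call. = FALSE)
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("I/O error: unsupported geometry type '", geom$type, "'",
           call. = FALSE))
    tibble::tibble(
      herd_id = id,
      x = vapply(ring, function(p) as.numeric(p[[1]]), numeric(1)),
      y = vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    )
  })
  herd_ranges(rows, crs_id = crs_id)
}

#' Write herd ranges to GeoJSON
#'
#' @param ranges A [herd_ranges()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_herd_ranges <- function(ranges, path) {
  stopifnot(inherits(ranges, "herd_ranges"))
  feats <- lapply(herd_ids(ranges), function(h) {
    ring <- range_polygon(ranges, h)
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(herd_id = h),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_id = attr(ranges, "crs_id"),
         features = feats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Class labels and matrix for either a trend_raster or a hotspot_raster.
class_layer <- function(classes) {
  if (inherits(classes, "trend_raster")) {
    list(grid = classes$grid, cls = classes$change_class,
         levels = c("increasing", "decreasing", "no_change"))
  } else if (inherits(classes, "hotspot_raster")) {
    list(grid = classes$grid, cls = classes$cluster_class,
         levels = c("positive_cluster", "negative_cluster", "no_cluster"))
  } else {
    stop("classes must be a trend_raster or hotspot_raster", call. = FALSE)
  }
}

#' Zonal class percentages per herd range
#'
#' For each herd, the percentage of classified lichen-mask pixels (cell
#' center inside the polygon) falling in each change/cluster class — the
#' per-herd change tables of the analysis. Percentages are over classified
#' lichen pixels only, so the classes of one herd always sum to 100.
#'
#' @param classes A [trend_raster()] or [gi_star()] result.
#' @param mask A [lichen_mask()] aligned with `classes`.
#' @param ranges A [herd_ranges()] in the raster CRS.
#' @return A tibble with columns `herd_id`, `class`, `n_pixels`, `pct`
#'   (classes in fixed order per herd).
#' @export
zonal_class_percentages <- function(classes, mask, ranges) {
  layer <- class_layer(classes)
  stopifnot(inherits(mask, "lichen_mask"), inherits(ranges, "herd_ranges"))
  assert_aligned(layer$grid, mask$grid, "class raster and mask")
  cc <- cell_centers(layer$grid)
  idx <- cbind(cc$row, cc$col)
  cls <- layer$cls[idx]
  eligible <- mask$is_lichen[idx] & !is.na(cls)
  assigned <- rep(FALSE, nrow(cc))  # first polygon in file order wins ties
  out <- purrr::map_dfr(herd_ids(ranges), function(h) {
    inside <- points_in_range(ranges, h, cc$x, cc$y) & !assigned
    assigned <<- assigned | inside
    keep <- inside & eligible
    if (!any(keep)) {
      stop("empty-zone error: herd '", h,
           "' contains no classified lichen pixels", call. = FALSE)
    }
    n <- unname(vapply(layer$levels, function(l) sum(cls[keep] == l),
                       numeric(1)))
    tibble::tibble(herd_id = h, class = layer$levels,
                   n_pixels = as.integer(n), pct = 100 * n / sum(n))
  })
  out
}

#' Spatially stratified random sample of a slope raster within a range
#'
#' Implements the "spatially stratified random sample" used before the herd
#' comparison: the herd polygon's bounding box is cut into a
#' `ceiling(sqrt(n))`-by-`ceiling(sqrt(n))` grid of strata, the `n` draws are
#' allocated to strata proportionally to each stratum's count of eligible
#' pixels (largest-remainder rounding, capped at the stratum count), and
#' cells are drawn uniformly without replacement within each stratum.
#' Eligible pixels have their center inside the polygon and a valid slope.
#' Deterministic given `seed`.
#'
#' @param slopes A [scalar_raster()] of Theil-Sen slopes.
#' @param ranges A [herd_ranges()].
#' @param herd Herd id to sample (default: all herds, stacked).
#' @param n Samples per herd (default 1000).
#' @param seed Integer seed.
#' @return A tibble `herd_id`, `row`, `col`, `x`, `y`, `slope`.
#' @export
stratified_sample <- function(slopes, ranges, herd = herd_ids(ranges),
                              n = 1000, seed = 1L) {
  stopifnot(inherits(slopes, "scalar_raster"), inherits(ranges, "herd_ranges"))
  if (length(herd) > 1) {
    return(purrr::map_dfr(seq_along(herd), function(i) {
      stratified_sample(slopes, ranges, herd[i], n = n, seed = seed + i - 1L)
    }))
  }
  cc <- cell_centers(slopes$grid)
  cc$slope <- slopes$values[cbind(cc$row, cc$col)]
  inside <- points_in_range(ranges, herd, cc$x, cc$y)
  cand <- cc[inside & !is.na(cc$slope), ]
  if (nrow(cand) < n) {
    stop("insufficient-data error: herd '", herd, "' has ", nrow(cand),
         " eligible pixels, need ", n, call. = FALSE)
  }
  g <- ceiling(sqrt(n))
  bx <- range(cand$x); by <- range(cand$y)
  # half-open strata, last bin closed
  sx <- pmin(floor((cand$x - bx[1]) / diff(bx) * g) + 1, g)
  sy <- pmin(floor((cand$y - by[1]) / diff(by) * g) + 1, g)
  if (diff(bx) == 0) sx[] <- 1
  if (diff(by) == 0) sy[] <- 1
  stratum <- (sy - 1) * g + sx
  counts <- tabulate(stratum, nbins = g * g)
  alloc <- largest_remainder(n * counts / sum(counts), n, cap = counts)
  rows <- with_seed(seed, {
    unlist(lapply(which(alloc > 0), function(st) {
      pool <- which(stratum == st)
      pool[sample.int(length(pool), alloc[st])]
    }))
  })
  out <- cand[sort(rows), c("row", "col", "x", "y", "slope")]
  dplyr::bind_cols(tibble::tibble(herd_id = herd), out)
}

# Largest-remainder apportionment of `total` into integer counts with target
# quotas `q` (summing to total) and per-cell caps. Cap overflow is
# redistributed to the largest remaining uncapped quotas.
largest_remainder <- function(q, total, cap = rep(Inf, length(q))) {
  stopifnot(abs(sum(q) - total) < 1e-8)
  a <- pmin(floor(q), cap)
  rem <- q - floor(q)
  left <- total - sum(a)
  while (left > 0) {
    open <- which(a < cap)
    if (!length(open)) stop("apportionment infeasible", call. = FALSE)
    ord <- open[order(rem[open], -a[open], decreasing = TRUE)]
    take <- ord[seq_len(min(left, length(ord)))]
    a[take] <- a[take] + 1
    rem[take] <- rem[take] - 1
    left <- total - sum(a)
  }
  a
}
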