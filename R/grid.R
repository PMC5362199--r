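#' Define a raster grid
#'
#' A `grid_spec` fixes the geometry every raster in an analysis must share:
#' grid dimensions, square cell size in metres, the projected coordinates of
#' the top-left corner, and a CRS identifier. Rows are counted from the top
#' (row 1 is the northernmost row), columns from the left, matching the usual
#' raster convention. Only projected, metre-unit systems are admitted because
#' the neighbourhood kernels and zonal sampling downstream assume uniform cell
#' area; pass a geographic CRS id (anything containing "EPSG:4326", "WGS84"
#' or "longlat") and construction fails.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres (square cells).
#' @param origin_x,origin_y Projected coordinates of the top-left corner of
#'   the top-left cell. `y` decreases southward (row index increases).
#' @param crs_id Free-text identifier of a projected CRS (e.g. `"EPSG:3978"`
#'   or a local tangent-plane id from [local_projection()]).
#' @return An object of class `grid_spec`.
#' @seealso [grids_aligned()], [cell_centers()], [scalar_raster()]
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_id = "LOCAL") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, is.finite(cell_size), cell_size > 0)
  if (grepl("4326|WGS ?84|longlat", crs_id, ignore.case = TRUE)) {
    stop("grid_spec: geographic CRS '", crs_id,
         "' rejected; analysis rasters must be in a projected, metre-unit CRS",
         call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m, origin (%.6g, %.6g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff all fields (dimensions, cell size, origin, CRS)
#' are equal; this is the equivalence relation enforced before any
#' cross-raster arithmetic.
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 0)) &&
    a$origin_x == b$origin_x && a$origin_y == b$origin_y &&
    a$crs_id == b$crs_id
}

assert_aligned <- function(a, b, what = "rasters") {
  if (!grids_aligned(a, b)) {
    stop("alignment error: ", what, " are on different grids", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y` (projected
#'   coordinates of the cell center), in row-major order.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    row = row, col = col,
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y - (row - 0.5) * grid$cell_size
  )
}

# Locate the cell containing each (x, y); returns row/col with NA outside the
# extent. Points exactly on a cell's top/left edge belong to that cell.
cells_at <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Single-band raster of real values
#'
#' The workhorse gridded container: a matrix of values on a [grid_spec()],
#' with `NA` marking invalid (nodata) cells. Values must be finite wherever
#' valid.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols`; `NA` encodes invalid cells.
#' @return An object of class `scalar_raster`.
#' @export
scalar_raster <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop("scalar_raster: values matrix does not match grid dimensions",
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values) | is.nan(values))) {
    stop("scalar_raster: non-finite values in valid cells; use NA for nodata",
         call. = FALSE)
  }
  structure(list(grid = grid, values = values), class = "scalar_raster")
}

#' @export
print.scalar_raster <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<scalar_raster> %d x %d (%d valid cells)\n",
              x$grid$n_rows, x$grid$n_cols, nv))
  if (nv > 0) {
    cat(sprintf("  range [%.6g, %.6g]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

#' @method as_tibble scalar_raster
#' @export
as_tibble.scalar_raster <- function(x, ...) {
  out <- cell_centers(x$grid)
  out$value <- as.vector(t(x$values))
  out
}

#' Boolean lichen-tundra mask
#'
#' Marks the cells where terricholous lichen tundra is present; only these
#' cells enter LVE scoring, trend detection and zonal summaries.
#'
#' @param grid A `grid_spec`.
#' @param is_lichen Logical matrix `n_rows x n_cols` (`NA` treated as `FALSE`).
#' @return An object of class `lichen_mask`.
#' @export
lichen_mask <- function(grid, is_lichen) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(is_lichen))
  if (!all(dim(is_lichen) == c(grid$n_rows, grid$n_cols))) {
    stop("lichen_mask: matrix does not match grid dimensions", call. = FALSE)
  }
  is_lichen <- matrix(as.logical(is_lichen), nrow(is_lichen), ncol(is_lichen))
  is_lichen[is.na(is_lichen)] <- FALSE
  structure(list(grid = grid, is_lichen = is_lichen), class = "lichen_mask")
}

#' @export
print.lichen_mask <- function(x, ...) {
  cat(sprintf("<lichen_mask> %d x %d (%d lichen cells, %.1f%%)\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$is_lichen),
              100 * mean(x$is_lichen)))
  invisible(x)
}

#' Multi-year, multi-band reflectance stack
#'
#' Annual surface-reflectance composites stacked over years, with the three
#' semantic bands the lichen volume estimator needs: `green`, `nir` and
#' `swir1`. Reflectances live in \[0, 1\]; a cell invalid in one year is
#' invalid in all bands of that year (encoded as `NA`).
#'
#' @param grid A `grid_spec`.
#' @param years Strictly increasing integer years.
#' @param values A 4-d array `[year, band, row, col]` with
#'   `dimnames[[2]] = c("green","nir","swir1")` (any order, all three present).
#' @return An object of class `reflectance_stack`.
#' @export
reflectance_stack <- function(grid, years, values) {
  stopifnot(inherits(grid, "grid_spec"), is.array(values), length(dim(values)) == 4)
  years <- as.integer(years)
  if (length(years) < 1 || is.unsorted(years, strictly = TRUE)) {
    stop("reflectance_stack: years must be strictly increasing", call. = FALSE)
  }
  bands <- dimnames(values)[[2]]
  if (is.null(bands) || !all(c("green", "nir", "swir1") %in% bands)) {
    stop("configuration error: bands green, nir and swir1 are all required",
         call. = FALSE)
  }
  if (!all(dim(values) == c(length(years), length(bands), grid$n_rows, grid$n_cols))) {
    stop("reflectance_stack: array does not match (years, bands, grid)",
         call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1)) {
    stop("reflectance_stack: reflectance outside [0, 1]", call. = FALSE)
  }
  structure(list(grid = grid, years = years, bands = bands, values = values),
            class = "reflectance_stack")
}

#' @export
print.reflectance_stack <- function(x, ...) {
  cat(sprintf("<reflectance_stack> %d years (%d-%d), bands %s, %d x %d\n",
              length(x$years), min(x$years), max(x$years),
              paste(x$bands, collapse = "/"), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# Band slice of one year as a plain matrix (NA where invalid).
stack_band <- function(stack, year, band) {
  iy <- match(year, stack$years)
  if (is.na(iy)) stop("year ", year, " not present in stack", call. = FALSE)
  ib <- match(band, stack$bands)
  if (is.na(ib)) stop("configuration error: band '", band, "' missing", call. = FALSE)
  matrix(stack$values[iy, ib, , ], stack$grid$n_rows, stack$grid$n_cols)
}

#' Resample a coarse mask to a finer grid by nearest neighbour
#'
#' Each target cell takes the value of the coarse cell containing its center
#' (cell-center lookup, well defined for non-integer resolution ratios such
#' as 250 m to 30 m). The coarse extent must cover every target cell center.
#'
#' @param coarse A `lichen_mask` on the coarse grid.
#' @param target A `grid_spec` describing the finer grid.
#' @return A `lichen_mask` on `target`.
#' @export
resample_mask_nearest <- function(coarse, target) {
  stopifnot(inherits(coarse, "lichen_mask"), inherits(target, "grid_spec"))
  cc <- cell_centers(target)
  at <- cells_at(coarse$grid, cc$x, cc$y)
  if (anyNA(at$row)) {
    stop("alignment error: target grid extends beyond the coarse mask extent",
         call. = FALSE)
  }
  vals <- coarse$is_lichen[cbind(at$row, at$col)]
  lichen_mask(target, matrix(vals, target$n_rows, target$n_cols, byrow = TRUE))
}
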