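#' Write a raster to an ESRI ASCII grid
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`), a plain-text format
#' read by every mainstream GIS, with the CRS id in a `.prj` sidecar next to
#' the grid. Values are written with 17 significant digits so that
#' write-then-read round-trips doubles bit-exactly; invalid cells are written
#' as the declared nodata value.
#'
#' @param r A [scalar_raster()].
#' @param path Output path (conventionally ending in `.asc`).
#' @param nodata Numeric nodata sentinel written for invalid cells.
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "scalar_raster"))
  g <- r$grid
  vals <- r$values
  if (any(vals == nodata, na.rm = TRUE)) {
    stop("write_raster: a valid cell equals the nodata sentinel ", nodata,
         "; choose another sentinel", call. = FALSE)
  }
  vals[is.na(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_x),
    sprintf("yllcorner %.17g", g$origin_y - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  )
  body <- apply(vals, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("I/O error: cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  prj <- sub("\\.asc$", "", path)
  writeLines(r$grid$crs_id, paste0(prj, ".prj"), sep = "\n")
  invisible(path)
}

#' Read a raster from an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_raster()] or any GIS.
#' @param crs_id CRS id to use when no `.prj` sidecar is present.
#' @return A [scalar_raster()]; cells equal to the file's nodata value are
#'   invalid (`NA`).
#' @export
read_raster <- function(path, crs_id = "LOCAL") {
  if (!file.exists(path)) {
    stop("I/O error: no such raster file '", path, "'", call. = FALSE)
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("I/O error: '", path, "' is not an ESRI ASCII grid", call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("I/O error: '", path, "' body has ", length(vals),
         " values, expected ", nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj_path <- paste0(sub("\\.asc$", "", path), ".prj")
  if (file.exists(prj_path)) crs_id <- readLines(prj_path, n = 1)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  g <- grid_spec(nr, nc, hdr$cellsize,
                 origin_x = xll, origin_y = yll + nr * hdr$cellsize,
                 crs_id = crs_id)
  scalar_raster(g, m)
}

#' Read yearly band files into a reflectance stack
#'
#' Takes a manifest of single-band raster files — one file per (year, band) —
#' and assembles a [reflectance_stack()]. The `band` column carries semantic
#' labels (`green`, `nir`, `swir1`); numeric sensor band indices are mapped to
#' labels by the caller (band semantics are configuration, never inferred from
#' metadata). All files must share one grid; a cell that is nodata in any band
#' of a year is invalid for that whole year.
#'
#' @param files A data frame with columns `path`, `year`, `band`.
#' @return A [reflectance_stack()].
#' @seealso [stack_files()] for the naming-convention helper,
#'   [write_stack()] for the inverse.
#' @export
read_stack <- function(files) {
  files <- tibble::as_tibble(files)
  stopifnot(all(c("path", "year", "band") %in% names(files)))
  files$year <- as.integer(files$year)
  years <- sort(unique(files$year))
  bands <- c("green", "nir", "swir1")
  missing <- setdiff(bands, unique(files$band))
  if (length(missing)) {
    stop("configuration error: no files for band(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  first <- read_raster(files$path[1])
  g <- first$grid
  vals <- array(NA_real_, c(length(years), length(bands), g$n_rows, g$n_cols),
                dimnames = list(NULL, bands, NULL, NULL))
  for (k in seq_len(nrow(files))) {
    r <- if (k == 1) first else read_raster(files$path[k])
    if (!grids_aligned(r$grid, g)) {
      stop("alignment error: '", files$path[k],
           "' is not on the grid of '", files$path[1], "'", call. = FALSE)
    }
    iy <- match(files$year[k], years)
    ib <- match(files$band[k], bands)
    if (is.na(ib)) {
      stop("configuration error: unknown band label '", files$band[k], "'",
           call. = FALSE)
    }
    vals[iy, ib, , ] <- r$values
  }
  # a nodata cell in any band invalidates the whole (year, cell)
  for (iy in seq_along(years)) {
    bad <- Reduce(`|`, lapply(seq_along(bands), function(ib) {
      is.na(matrix(vals[iy, ib, , ], g$n_rows, g$n_cols))
    }))
    for (ib in seq_along(bands)) {
      slice <- matrix(vals[iy, ib, , ], g$n_rows, g$n_cols)
      slice[bad] <- NA_real_
      vals[iy, ib, , ] <- slice
    }
  }
  reflectance_stack(g, years, vals)
}

#' Write a reflectance stack as per-(year, band) ASCII grids
#'
#' Files are named `<prefix>_<year>_<band>.asc` under `dir`.
#'
#' @param stack A [reflectance_stack()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return The file manifest (tibble `path`, `year`, `band`), invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "refl") {
  stopifnot(inherits(stack, "reflectance_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- tidyr::expand_grid(year = stack$years, band = stack$bands)
  out$path <- file.path(dir, sprintf("%s_%d_%s.asc", prefix, out$year, out$band))
  for (k in seq_len(nrow(out))) {
    write_raster(scalar_raster(stack$grid,
                               stack_band(stack, out$year[k], out$band[k])),
                 out$path[k])
  }
  invisible(out[, c("path", "year", "band")])
}

#' Build a read_stack() manifest from file names
#'
#' Matches `<anything>_<year>_<band>.asc` in `dir`.
#'
#' @param dir Directory holding per-(year, band) `.asc` files.
#' @return A tibble with columns `path`, `year`, `band`.
#' @export
stack_files <- function(dir) {
  paths <- list.files(dir, pattern = "_[0-9]{4}_(green|nir|swir1)\\.asc$",
                      full.names = TRUE)
  if (!length(paths)) {
    stop("I/O error: no *_<year>_<band>.asc files in '", dir, "'", call. = FALSE)
  }
  m <- regmatches(paths, regexec("_([0-9]{4})_(green|nir|swir1)\\.asc$", paths))
  tibble::tibble(
    path = paths,
    year = as.integer(vapply(m, `[`, "", 2)),
    band = vapply(m, `[`, "", 3)
  )
}
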