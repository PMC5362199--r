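#' Normalized difference lichen index
#'
#' `(swir1 - green) / (swir1 + green)`, sensitive to the spectral signature
#' of terricholous lichen mats. Vectorised; a zero denominator yields `NA`
#' (an invalid marker, never an error).
#'
#' @param swir1,green Surface reflectance in \[0, 1\] (scalars, vectors or
#'   matrices of equal shape).
#' @return Unitless index in \[-1, 1\], `NA` where undefined.
#' @export
ndli <- function(swir1, green) {
  den <- swir1 + green
  out <- (swir1 - green) / den
  out[den == 0] <- NA_real_
  out
}

#' Normalized difference moisture index
#'
#' `(nir - swir1) / (nir + swir1)`, a proxy for vegetation moisture.
#'
#' @param nir,swir1 Surface reflectance in \[0, 1\].
#' @return Unitless index in \[-1, 1\], `NA` where undefined.
#' @export
ndmi <- function(nir, swir1) {
  den <- nir + swir1
  out <- (nir - swir1) / den
  out[den == 0] <- NA_real_
  out
}

#' Parameters of the lichen volume estimator
#'
#' The LVE scores each pixel by a correlated two-dimensional Gaussian over
#' the (NDLI, NDMI) plane: the score peaks at `amplitude` where both indices
#' sit at the Gaussian center and decays with the Mahalanobis-type quadratic
#' form of the standardized index deviations. The coefficients published for
#' the original Norwegian calibration are not reproduced here; the defaults
#' below are **placeholders** that fix a usable scale (peak 100, centered
#' index space, sd 0.25, no correlation) and must be replaced with calibrated
#' values for any absolute interpretation. All output is a relative index.
#'
#' @param amplitude Peak LVE score (> 0).
#' @param mu_ndli,mu_ndmi Gaussian center in index units (used directly when
#'   `center_mode = "fixed"`).
#' @param sigma_ndli,sigma_ndmi Gaussian spreads in index units (> 0).
#' @param rho Correlation between the two index deviations, in (-1, 1).
#' @param center_mode `"scene_mean"` (default) centers the Gaussian on the
#'   scene-wide masked mean indices; `"fixed"` uses `mu_ndli`/`mu_ndmi`.
#' @return An object of class `lve_params`.
#' @export
lve_params <- function(amplitude = 100, mu_ndli = 0, mu_ndmi = 0,
                       sigma_ndli = 0.25, sigma_ndmi = 0.25, rho = 0,
                       center_mode = c("scene_mean", "fixed")) {
  center_mode <- match.arg(center_mode)
  stopifnot(amplitude > 0, sigma_ndli > 0, sigma_ndmi > 0, abs(rho) < 1)
  structure(
    list(amplitude = amplitude, mu_ndli = mu_ndli, mu_ndmi = mu_ndmi,
         sigma_ndli = sigma_ndli, sigma_ndmi = sigma_ndmi, rho = rho,
         center_mode = center_mode),
    class = "lve_params"
  )
}

#' @export
print.lve_params <- function(x, ...) {
  cat(sprintf(
    "<lve_params> amplitude %.4g, mu (%.4g, %.4g), sigma (%.4g, %.4g), rho %.4g, center %s\n",
    x$amplitude, x$mu_ndli, x$mu_ndmi, x$sigma_ndli, x$sigma_ndmi, x$rho,
    x$center_mode))
  invisible(x)
}

#' Scene-wide masked mean indices for one year
#'
#' Mean NDLI and NDMI over the cells that are valid in the stack for that
#' year and flagged lichen in the mask — the centering statistics the
#' scene-mean LVE mode requires.
#'
#' @param stack A [reflectance_stack()].
#' @param mask A [lichen_mask()] aligned with the stack.
#' @param year Year present in the stack.
#' @return A one-row tibble with columns `year`, `ndli`, `ndmi`, `n_cells`.
#' @export
scene_index_means <- function(stack, mask, year) {
  stopifnot(inherits(stack, "reflectance_stack"), inherits(mask, "lichen_mask"))
  assert_aligned(stack$grid, mask$grid, "stack and mask")
  g <- stack_band(stack, year, "green")
  n <- stack_band(stack, year, "nir")
  s <- stack_band(stack, year, "swir1")
  keep <- mask$is_lichen & !is.na(g)
  if (!any(keep)) {
    stop("empty-domain error: no valid lichen cells in year ", year,
         call. = FALSE)
  }
  tibble::tibble(
    year = as.integer(year),
    ndli = mean(ndli(s[keep], g[keep]), na.rm = TRUE),
    ndmi = mean(ndmi(n[keep], s[keep]), na.rm = TRUE),
    n_cells = sum(keep)
  )
}

#' Score the two-dimensional Gaussian LVE
#'
#' With standardized deviations `u = (ndli - c_ndli)/sigma_ndli` and
#' `v = (ndmi - c_ndmi)/sigma_ndmi` about the center `c`, the score is
#' `amplitude * exp(-(u^2 - 2*rho*u*v + v^2) / (2*(1 - rho^2)))`,
#' in (0, amplitude].
#'
#' @param ndli,ndmi Index values (vectorised).
#' @param params An [lve_params()].
#' @param center Numeric `c(ndli, ndmi)` center; defaults to the fixed
#'   `mu` pair in `params`.
#' @return LVE scores, same shape as the inputs.
#' @export
lve_score <- function(ndli, ndmi, params,
                      center = c(params$mu_ndli, params$mu_ndmi)) {
  stopifnot(inherits(params, "lve_params"), length(center) == 2)
  u <- (ndli - center[1]) / params$sigma_ndli
  v <- (ndmi - center[2]) / params$sigma_ndmi
  q <- (u^2 - 2 * params$rho * u * v + v^2) / (1 - params$rho^2)
  params$amplitude * exp(-q / 2)
}

#' Annual LVE rasters from a reflectance stack
#'
#' For each year: compute NDLI and NDMI per cell, center the Gaussian (on the
#' year's scene-wide masked means, a single all-years mean, or the fixed `mu`
#' pair), and score every lichen-mask cell. Non-lichen and invalid cells are
#' invalid in the output.
#'
#' @param stack A [reflectance_stack()].
#' @param mask A [lichen_mask()] aligned with the stack.
#' @param params An [lve_params()]; `params$center_mode` selects centering.
#' @param center_scope With `center_mode = "scene_mean"`: `"year"` (default)
#'   recenters each year on its own scene means, `"stack"` centers every year
#'   on the mean of the yearly scene means.
#' @return A named list of [scalar_raster()] (names = years), of class
#'   `lve_stack`, with the per-year centers in `attr(, "centers")`.
#' @export
lve_stack <- function(stack, mask, params = lve_params(),
                      center_scope = c("year", "stack")) {
  stopifnot(inherits(stack, "reflectance_stack"), inherits(mask, "lichen_mask"),
            inherits(params, "lve_params"))
  center_scope <- match.arg(center_scope)
  assert_aligned(stack$grid, mask$grid, "stack and mask")

  centers <- NULL
  if (params$center_mode == "scene_mean") {
    centers <- dplyr::bind_rows(
      lapply(stack$years, function(y) scene_index_means(stack, mask, y)))
    if (center_scope == "stack") {
      centers$ndli <- mean(centers$ndli)
      centers$ndmi <- mean(centers$ndmi)
    }
  } else {
    centers <- tibble::tibble(year = stack$years,
                              ndli = params$mu_ndli, ndmi = params$mu_ndmi,
                              n_cells = NA_integer_)
  }

  out <- lapply(seq_along(stack$years), function(iy) {
    y <- stack$years[iy]
    g <- stack_band(stack, y, "green")
    n <- stack_band(stack, y, "nir")
    s <- stack_band(stack, y, "swir1")
    li <- ndli(s, g)
    mi <- ndmi(n, s)
    sc <- lve_score(li, mi, params,
                    center = c(centers$ndli[iy], centers$ndmi[iy]))
    sc[!mask$is_lichen | is.na(li) | is.na(mi)] <- NA_real_
    scalar_raster(stack$grid, sc)
  })
  names(out) <- stack$years
  structure(out, class = "lve_stack", centers = centers)
}

#' @export
print.lve_stack <- function(x, ...) {
  cat(sprintf("<lve_stack> %d yearly LVE rasters (%s-%s)\n",
              length(x), names(x)[1], names(x)[length(x)]))
  invisible(x)
}
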