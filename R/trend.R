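#' Theil-Sen slope of a time series
#'
#' The median over all `n(n-1)/2` pairwise slopes
#' `(x_j - x_i) / (t_j - t_i)`, `i < j` — a robust estimator of yearly
#' change that tolerates outliers far better than least squares. With an
#' even pair count the two middle slopes are averaged (the standard median).
#'
#' @param x Numeric values (e.g. yearly LVE).
#' @param t Strictly increasing numeric times (default `1:n`).
#' @return The median pairwise slope, in `x` units per `t` unit.
#' @export
theil_sen_slope <- function(x, t = seq_along(x)) {
  n <- length(x)
  if (n < 2) {
    stop("insufficient-data error: Theil-Sen needs at least 2 observations",
         call. = FALSE)
  }
  stopifnot(length(t) == n, !is.unsorted(t, strictly = TRUE), all(is.finite(x)))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  stats::median((x[ij[, 2]] - x[ij[, 1]]) / (t[ij[, 2]] - t[ij[, 1]]))
}

#' Mann-Kendall trend test
#'
#' The rank-based test for a monotone trend. `S` is the sum of
#' `sign(x_j - x_i)` over all ordered pairs; its null variance carries the
#' standard tie correction
#' `Var(S) = [n(n-1)(2n+5) - sum_k t_k(t_k-1)(2t_k+5)] / 18`
#' over tie groups of size `t_k`, and the z-score applies the continuity
#' correction (`(S-1)/sd` for positive `S`, `(S+1)/sd` for negative). A
#' fully tied series (zero variance) is reported as `S = 0`, `z = 0`,
#' `p = 1` rather than an error.
#'
#' @param x Numeric values.
#' @param t Strictly increasing times (only their order matters; default `1:n`).
#' @param min_n Minimum series length (default 4).
#' @return A one-row tibble: `n`, `s` (integer S), `var_s`, `z`, `p_value`
#'   (two-sided normal).
#' @export
mann_kendall <- function(x, t = seq_along(x), min_n = 4) {
  n <- length(x)
  if (n < min_n) {
    stop("insufficient-data error: Mann-Kendall needs at least ", min_n,
         " observations", call. = FALSE)
  }
  stopifnot(length(t) == n, !is.unsorted(t, strictly = TRUE), all(is.finite(x)))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  s <- sum(sign(x[ij[, 2]] - x[ij[, 1]]))
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_s <= 0) {
    return(tibble::tibble(n = n, s = 0L, var_s = 0, z = 0, p_value = 1))
  }
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  tibble::tibble(n = n, s = as.integer(s), var_s = var_s, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Per-pixel trend raster from yearly LVE
#'
#' Runs Theil-Sen and Mann-Kendall on every pixel's valid-year subseries and
#' classifies each pixel at significance level `alpha`: `increasing`
#' (positive slope, p < alpha), `decreasing` (negative slope, p < alpha),
#' `no_change` otherwise. Pixels with fewer than `min_years` valid years are
#' `invalid`. No multiple-testing correction is applied across pixels
#' (per-pixel classification at `alpha` is the convention this pipeline
#' follows); `p_adjust = "fdr"` switches on a Benjamini-Hochberg adjustment
#' over the valid pixels before classification.
#'
#' @param lve_by_year A named list of aligned [scalar_raster()] (names =
#'   years), e.g. an [lve_stack()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param min_years Minimum valid years per pixel (default 10).
#' @param p_adjust `"none"` (default) or `"fdr"`.
#' @return An object of class `trend_raster`: list with `grid` and matrices
#'   `slope`, `mk_s`, `mk_z`, `p_value`, plus `change_class` (character
#'   matrix) and the settings used.
#' @export
trend_raster <- function(lve_by_year, alpha = 0.05, min_years = 10,
                         p_adjust = c("none", "fdr")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(lve_by_year) >= 2, !is.null(names(lve_by_year)))
  years <- as.integer(names(lve_by_year))
  stopifnot(!anyNA(years), !is.unsorted(years, strictly = TRUE))
  g <- lve_by_year[[1]]$grid
  for (r in lve_by_year) assert_aligned(r$grid, g, "yearly LVE rasters")

  npx <- g$n_rows * g$n_cols
  ny <- length(years)
  # Y: years x pixels (pixels in column-major cell order of the matrices)
  Y <- do.call(rbind, lapply(lve_by_year, function(r) as.vector(r$values)))
  nvalid <- colSums(!is.na(Y))
  use <- nvalid >= max(min_years, 2L)

  slope <- mk_s <- mk_z <- pval <- rep(NA_real_, npx)
  if (any(use)) {
    ij <- which(upper.tri(matrix(0, ny, ny)), arr.ind = TRUE)
    dt <- years[ij[, 2]] - years[ij[, 1]]
    npair <- nrow(ij)
    Yu <- Y[, use, drop = FALSE]
    D <- Yu[ij[, 2], , drop = FALSE] - Yu[ij[, 1], , drop = FALSE]  # pairwise diffs
    P <- D / dt
    slope[use] <- apply(P, 2, stats::median, na.rm = TRUE)
    s_vec <- colSums(sign(D), na.rm = TRUE)
    mk_s[use] <- s_vec

    n_u <- nvalid[use]
    tie_term <- vapply(seq_len(ncol(Yu)), function(k) {
      xv <- Yu[, k]
      xv <- xv[!is.na(xv)]
      if (anyDuplicated(xv) == 0) return(0)
      tk <- table(xv)
      tk <- tk[tk > 1]
      sum(tk * (tk - 1) * (2 * tk + 5))
    }, numeric(1))
    var_s <- (n_u * (n_u - 1) * (2 * n_u + 5) - tie_term) / 18
    z <- numeric(length(s_vec))
    pos <- var_s > 0 & s_vec > 0
    neg <- var_s > 0 & s_vec < 0
    z[pos] <- (s_vec[pos] - 1) / sqrt(var_s[pos])
    z[neg] <- (s_vec[neg] + 1) / sqrt(var_s[neg])
    p <- 2 * stats::pnorm(-abs(z))
    p[var_s <= 0] <- 1
    mk_z[use] <- z
    pval[use] <- p
  }

  if (p_adjust == "fdr") {
    pval[use] <- stats::p.adjust(pval[use], method = "BH")
  }

  cls <- rep(NA_character_, npx)
  cls[use] <- "no_change"
  cls[use & pval < alpha & slope > 0] <- "increasing"
  cls[use & pval < alpha & slope < 0] <- "decreasing"

  shape <- function(v) matrix(v, g$n_rows, g$n_cols)
  structure(
    list(grid = g,
         slope = shape(slope), mk_s = shape(mk_s), mk_z = shape(mk_z),
         p_value = shape(pval), change_class = shape(cls),
         years = years, alpha = alpha, min_years = min_years,
         p_adjust = p_adjust),
    class = "trend_raster"
  )
}

#' @export
print.trend_raster <- function(x, ...) {
  tab <- table(factor(x$change_class,
                      c("increasing", "decreasing", "no_change")))
  cat(sprintf("<trend_raster> %d x %d, %d years, alpha %.3g\n",
              x$grid$n_rows, x$grid$n_cols, length(x$years), x$alpha))
  cat(sprintf("  increasing %d | decreasing %d | no_change %d | invalid %d\n",
              tab[1], tab[2], tab[3], sum(is.na(x$change_class))))
  invisible(x)
}

#' @method tidy trend_raster
#' @export
tidy.trend_raster <- function(x, ...) {
  out <- cell_centers(x$grid)
  idx <- cbind(out$row, out$col)
  out$slope <- x$slope[idx]
  out$mk_s <- x$mk_s[idx]
  out$mk_z <- x$mk_z[idx]
  out$p_value <- x$p_value[idx]
  out$change_class <- x$change_class[idx]
  out$change_class[is.na(out$change_class)] <- "invalid"
  out
}

#' Extract the Theil-Sen slope layer of a trend raster
#'
#' @param x A [trend_raster()].
#' @return A [scalar_raster()] of slopes (LVE units per year).
#' @export
slope_raster <- function(x) {
  stopifnot(inherits(x, "trend_raster"))
  scalar_raster(x$grid, x$slope)
}
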