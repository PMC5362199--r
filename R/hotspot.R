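# 3x3 Queen's-case neighbourhood sums (self included), truncated at grid
# edges and at invalid cells. Returns the neighbour sum and count per cell.
queen_sums <- function(values) {
  nr <- nrow(values); nc <- ncol(values)
  v0 <- values
  v0[is.na(v0)] <- 0
  valid <- !is.na(values) * 1
  pad <- function(m) {
    out <- matrix(0, nr + 2, nc + 2)
    out[2:(nr + 1), 2:(nc + 1)] <- m
    out
  }
  pv <- pad(v0); pc <- pad(valid)
  s <- matrix(0, nr, nc); w <- matrix(0, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      rows <- (2 + dr):(nr + 1 + dr)
      cols <- (2 + dc):(nc + 1 + dc)
      s <- s + pv[rows, cols]
      w <- w + pc[rows, cols]
    }
  }
  list(sum = s, count = w)
}

#' Getis-Ord Gi* hotspot raster
#'
#' Local spatial autocorrelation of a value raster (typically the Theil-Sen
#' slope layer): for each valid pixel `i`, the 3x3 Queen's-case neighbourhood
#' including the focal pixel (that self-inclusion is what the star denotes)
#' is summed with binary weights and compared with its expectation under the
#' global mean, standardised by the Getis-Ord variance:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{(n W_i - W_i^2) / (n - 1)}}}
#' where `W_i` is the number of valid neighbours (the kernel truncates at
#' edges and nodata holes), and the global mean and standard deviation
#' (denominator `n`) are taken over **all** valid pixels of the raster. The
#' result is a z-score: large positive values mark pixels centered in
#' clusters of high values, large negative values clusters of low values.
#'
#' @param slopes A [scalar_raster()] with at least 2 valid pixels and
#'   nonzero variance.
#' @param z_crit Two-sided critical z for classification (default 1.96,
#'   i.e. alpha = 0.05).
#' @return An object of class `hotspot_raster`: `grid`, matrix `gi_z`, and
#'   character matrix `cluster_class` in
#'   `{positive_cluster, negative_cluster, no_cluster}` (`NA` = invalid).
#' @export
gi_star <- function(slopes, z_crit = 1.96) {
  stopifnot(inherits(slopes, "scalar_raster"))
  x <- slopes$values
  vals <- x[!is.na(x)]
  n <- length(vals)
  if (n < 2) {
    stop("degenerate-input error: Gi* needs at least 2 valid pixels",
         call. = FALSE)
  }
  xbar <- mean(vals)
  s_glob <- sqrt(mean(vals^2) - xbar^2)  # denominator-n sd
  if (s_glob <= 0 || !is.finite(s_glob)) {
    stop("degenerate-input error: zero global variance in Gi* input",
         call. = FALSE)
  }
  q <- queen_sums(x)
  wi <- q$count
  denom <- s_glob * sqrt((n * wi - wi^2) / (n - 1))
  gz <- (q$sum - xbar * wi) / denom
  gz[is.na(x)] <- NA_real_
  # W_i = n (tiny rasters fully inside one kernel) makes the variance 0
  gz[!is.na(x) & wi >= n] <- 0
  h <- structure(list(grid = slopes$grid, gi_z = gz,
                      cluster_class = matrix(NA_character_, nrow(x), ncol(x)),
                      z_crit = z_crit),
                 class = "hotspot_raster")
  classify_clusters(h, z_crit)
}

#' Reclassify a hotspot raster at a new critical z
#'
#' `positive_cluster` where `gi_z > z_crit`, `negative_cluster` where
#' `gi_z < -z_crit`, `no_cluster` otherwise (two-sided normal criterion).
#'
#' @param h A `hotspot_raster` from [gi_star()].
#' @param z_crit Critical value (default 1.96).
#' @return The reclassified `hotspot_raster`.
#' @export
classify_clusters <- function(h, z_crit = 1.96) {
  stopifnot(inherits(h, "hotspot_raster"), z_crit >= 0)
  cls <- matrix(NA_character_, nrow(h$gi_z), ncol(h$gi_z))
  ok <- !is.na(h$gi_z)
  cls[ok] <- "no_cluster"
  cls[ok & h$gi_z > z_crit] <- "positive_cluster"
  cls[ok & h$gi_z < -z_crit] <- "negative_cluster"
  h$cluster_class <- cls
  h$z_crit <- z_crit
  h
}

#' @export
print.hotspot_raster <- function(x, ...) {
  tab <- table(factor(x$cluster_class,
                      c("positive_cluster", "negative_cluster", "no_cluster")))
  cat(sprintf("<hotspot_raster> %d x %d, z_crit %.3g\n",
              x$grid$n_rows, x$grid$n_cols, x$z_crit))
  cat(sprintf("  positive %d | negative %d | none %d | invalid %d\n",
              tab[1], tab[2], tab[3], sum(is.na(x$cluster_class))))
  invisible(x)
}

#' @method tidy hotspot_raster
#' @export
tidy.hotspot_raster <- function(x, ...) {
  out <- cell_centers(x$grid)
  idx <- cbind(out$row, out$col)
  out$gi_z <- x$gi_z[idx]
  out$cluster_class <- x$cluster_class[idx]
  out$cluster_class[is.na(out$cluster_class)] <- "invalid"
  out
}
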