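#' Simulate spatially correlated herd slope samples
#'
#' Draws per-herd slope samples with the spatial structure the GLS herd
#' comparison assumes: herds occupy adjacent square blocks, sample locations
#' are spatially stratified (one jittered point per cell of a regular grid,
#' mirroring [stratified_sample()]'s design), and the noise field is a
#' Gaussian process with the Gaussian correlogram
#' `corr(d) = (1 - nugget) * exp(-(d / range_m)^2)` plus a nugget, simulated
#' exactly by Cholesky factorisation. Herd means are added on top, so the
#' same generator serves null-calibration (equal means) and
#' parameter-recovery (unequal means) experiments.
#'
#' @param means Numeric vector of true herd mean slopes (length = number of
#'   herds).
#' @param grid_per_herd Stratification grid edge; each herd gets
#'   `grid_per_herd^2` samples.
#' @param side Herd block edge length in metres (default 10 km).
#' @param range_m Gaussian correlogram range in metres.
#' @param nugget Nugget fraction of unit total variance, in \[0, 1).
#' @param sd Marginal standard deviation of the noise field.
#' @param seed Seed.
#' @return A tibble `herd_id`, `x`, `y`, `slope` (plus `mu_true`), ready for
#'   [gls_herd_model()].
#' @export
simulate_herd_samples <- function(means = c(0, 0, 0), grid_per_herd = 7,
                                  side = 10000, range_m = 800,
                                  nugget = 0.2, sd = 1, seed = 1L) {
  k <- length(means)
  stopifnot(k >= 2, nugget >= 0, nugget < 1, range_m > 0)
  g <- grid_per_herd
  n <- g * g
  with_seed(seed, {
    xs <- ys <- numeric(0)
    for (h in seq_len(k)) {
      gx <- rep(seq_len(g), each = g)
      gy <- rep(seq_len(g), times = g)
      xs <- c(xs, (h - 1) * side + (gx - stats::runif(n)) * side / g)
      ys <- c(ys, (gy - stats::runif(n)) * side / g)
    }
    D <- as.matrix(stats::dist(cbind(xs, ys)))
    C <- sd^2 * ((1 - nugget) * exp(-(D / range_m)^2) + diag(nugget, k * n))
    z <- drop(t(chol(C)) %*% stats::rnorm(k * n))
    mu <- rep(means, each = n)
    tibble::tibble(
      herd_id = rep(sprintf("herd_%02d", seq_len(k)), each = n),
      x = xs, y = ys, slope = mu + z, mu_true = mu
    )
  })
}
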