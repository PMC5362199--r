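#' @importFrom ggplot2 autoplot
NULL

#' Plot a scalar raster
#'
#' @param object A [scalar_raster()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot scalar_raster
#' @export
autoplot.scalar_raster <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a trend classification map
#'
#' @param object A [trend_raster()].
#' @param ... Ignored.
#' @return A ggplot of the change classes.
#' @method autoplot trend_raster
#' @export
autoplot.trend_raster <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$change_class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      increasing = "#2166ac", decreasing = "#b2182b",
      no_change = "grey80", invalid = "grey95"), name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Theil-Sen change classes (alpha = %.2g)",
                                  object$alpha))
}

#' Plot a Gi* cluster map
#'
#' @param object A `hotspot_raster` from [gi_star()].
#' @param ... Ignored.
#' @return A ggplot of the cluster classes.
#' @method autoplot hotspot_raster
#' @export
autoplot.hotspot_raster <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$cluster_class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      positive_cluster = "#2166ac", negative_cluster = "#b2182b",
      no_cluster = "grey80", invalid = "grey95"), name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Gi* clusters (|z| > %.2f)", object$z_crit))
}

#' Plot a fitted velocity-LVE curve
#'
#' Mean predicted movement velocity against LVE with a one-standard-error
#' ribbon, the standard way the seasonal association is displayed.
#'
#' @param object A [fit_velocity_smooth()] result.
#' @param ... Passed to [predict_curve()].
#' @return A ggplot.
#' @method autoplot velocity_smooth
#' @export
autoplot.velocity_smooth <- function(object, ...) {
  d <- predict_curve(object, ...)
  ggplot2::ggplot(d, ggplot2::aes(.data$lve, .data$velocity)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "LVE", y = "Mean velocity (m/h)",
                  title = sprintf("Season: %s", object$season))
}

#' Boxplot of herd slope samples
#'
#' @param object A [gls_herd_model()] fit.
#' @param ... Ignored.
#' @return A ggplot of sampled Theil-Sen slopes by herd.
#' @method autoplot gls_herd_fit
#' @export
autoplot.gls_herd_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$herd_id, .data$slope)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Theil-Sen slope (LVE/yr)")
}

#' Velocity boxplots by herd and season
#'
#' @param steps A step tibble with `herd`, `season`, `velocity`.
#' @return A ggplot faceted by season.
#' @export
plot_velocity_summary <- function(steps) {
  d <- tibble::as_tibble(steps)
  d$season <- factor(d$season, c("spring", "summer", "fall", "winter"))
  ggplot2::ggplot(d, ggplot2::aes(.data$herd, .data$velocity)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::facet_wrap(~season) +
    ggplot2::coord_cartesian(
      ylim = c(0, stats::quantile(d$velocity, 0.98))) +
    ggplot2::labs(x = NULL, y = "Velocity (m/h)")
}
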