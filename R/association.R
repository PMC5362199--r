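#' Seasonal smooth of movement velocity on LVE
#'
#' Fits, for one season's steps, the overdispersed count model
#' `velocity ~ NB(mu, theta)`, `log(mu) = s(LVE) + b_animal`,
#' where `s` is a cubic B-spline smooth (default 8 basis functions,
#' second-difference penalty) with smoothing parameter chosen by maximum
#' likelihood, and `b_animal` are per-animal random intercepts fitted as a
#' penalized (ridge) smooth — the standard GAMM-via-mgcv formulation.
#' Velocities are rounded to integer m/h to admit the negative-binomial
#' count family (a documented convention; the rounding error is negligible
#' at caribou speeds). Residual spatial correlation is not modelled inside
#' the GAMM; inspect it with [residual_semivariogram()].
#'
#' @param steps A step tibble with `velocity`, `lve_at_start`, `animal_id`
#'   (typically pre-filtered to one season).
#' @param season Label stored on the fit (default: the single season present,
#'   else `"all"`).
#' @param k Basis dimension of the LVE smooth (default 8).
#' @param sp Optional fixed smoothing parameter; `NULL` (default) estimates
#'   it by ML.
#' @param min_steps,min_animals Data floor below which fitting refuses
#'   (defaults 50 and 3, relaxable for toy examples).
#' @return An object of class `velocity_smooth`: the [mgcv::gam()] fit plus
#'   `season`, `theta` (NB size), `smooth_f`/`smooth_p` (approximate test of
#'   the LVE smooth), `edf`, `lve_range`, `n_steps`, `n_animals`.
#' @export
fit_velocity_smooth <- function(steps, season = NULL, k = 8, sp = NULL,
                                min_steps = 50, min_animals = 3) {
  d <- tibble::as_tibble(steps)
  stopifnot(all(c("velocity", "lve_at_start", "animal_id") %in% names(d)))
  d <- d[!is.na(d$lve_at_start) & !is.na(d$velocity), ]
  if (is.null(season)) {
    season <- if ("season" %in% names(d) &&
                  length(unique(d$season)) == 1) d$season[1] else "all"
  }
  if (nrow(d) < min_steps) {
    stop("insufficient-data error: ", nrow(d), " usable steps, need >= ",
         min_steps, call. = FALSE)
  }
  n_animals <- length(unique(d$animal_id))
  if (n_animals < min_animals) {
    stop("insufficient-data error: ", n_animals, " animals, need >= ",
         min_animals, call. = FALSE)
  }
  if (length(unique(d$lve_at_start)) < 2) {
    stop("degenerate-covariate error: a single LVE value in the data",
         call. = FALSE)
  }
  d$vel_count <- as.integer(round(d$velocity))
  d$animal_id <- factor(d$animal_id)

  use_re <- n_animals >= 2
  form <- if (use_re) {
    vel_count ~ s(lve_at_start, bs = "bs", k = k, m = c(3, 2)) +
      s(animal_id, bs = "re")
  } else {
    vel_count ~ s(lve_at_start, bs = "bs", k = k, m = c(3, 2))
  }
  fit <- tryCatch(
    mgcv::gam(form, data = d, family = mgcv::nb(), method = "ML",
              sp = if (is.null(sp)) NULL else c(sp, rep(-1, use_re))),
    error = function(e) stop("fit error: GAMM did not converge (",
                             conditionMessage(e), ")", call. = FALSE))
  st <- summary(fit)$s.table
  stat_col <- intersect(c("F", "Chi.sq"), colnames(st))[1]
  structure(
    list(model = fit, season = season, k = k,
         theta = fit$family$getTheta(TRUE),
         smooth_f = st[1, stat_col], smooth_p = st[1, "p-value"],
         edf = st[1, "edf"],
         lve_range = range(d$lve_at_start),
         n_steps = nrow(d), n_animals = n_animals, random_effect = use_re),
    class = "velocity_smooth"
  )
}

#' @export
print.velocity_smooth <- function(x, ...) {
  cat(sprintf("<velocity_smooth> season %s: %d steps, %d animals\n",
              x$season, x$n_steps, x$n_animals))
  cat(sprintf("  s(LVE): edf %.2f, F = %.3f, p = %.3g; NB theta %.3g\n",
              x$edf, x$smooth_f, x$smooth_p, x$theta))
  invisible(x)
}

#' @method glance velocity_smooth
#' @export
glance.velocity_smooth <- function(x, ...) {
  tibble::tibble(
    season = x$season, n_steps = x$n_steps, n_animals = x$n_animals,
    edf = x$edf, smooth_f = x$smooth_f, smooth_p = x$smooth_p,
    theta = x$theta, lve_min = x$lve_range[1], lve_max = x$lve_range[2]
  )
}

#' Population-level predicted velocity curve
#'
#' Inverse-link predictions of mean velocity over an LVE grid at the
#' population level (random intercepts set to zero), with delta-method
#' standard errors and one-SE bounds. Grid points beyond the fitted LVE
#' range are flagged and trigger a warning but are still returned.
#'
#' @param fit A [fit_velocity_smooth()] result.
#' @param lve_grid Numeric grid (default: 100 points across the fitted
#'   range).
#' @return A tibble: `lve`, `velocity` (mean, m/h), `se`, `lower`, `upper`
#'   (mean -/+ 1 SE), `extrapolated`.
#' @export
predict_curve <- function(fit, lve_grid = NULL) {
  stopifnot(inherits(fit, "velocity_smooth"))
  if (is.null(lve_grid)) {
    lve_grid <- seq(fit$lve_range[1], fit$lve_range[2], length.out = 100)
  }
  extrap <- lve_grid < fit$lve_range[1] | lve_grid > fit$lve_range[2]
  if (any(extrap)) {
    warning("predict_curve: ", sum(extrap),
            " grid point(s) outside the fitted LVE range")
  }
  pr <- if (fit$random_effect) {
    nd <- data.frame(lve_at_start = lve_grid,
                     animal_id = fit$model$model$animal_id[1])
    mgcv::predict.gam(fit$model, newdata = nd, type = "link", se.fit = TRUE,
                      exclude = "s(animal_id)", newdata.guaranteed = TRUE)
  } else {
    mgcv::predict.gam(fit$model, newdata = data.frame(lve_at_start = lve_grid),
                      type = "link", se.fit = TRUE)
  }
  mu <- exp(as.numeric(pr$fit))
  se <- mu * as.numeric(pr$se.fit)  # delta method on the log link
  tibble::tibble(lve = lve_grid, velocity = mu, se = se,
                 lower = exp(as.numeric(pr$fit) - as.numeric(pr$se.fit)) ,
                 upper = exp(as.numeric(pr$fit) + as.numeric(pr$se.fit)),
                 extrapolated = extrap)
}

#' @method tidy velocity_smooth
#' @export
tidy.velocity_smooth <- function(x, ...) {
  predict_curve(x)
}

#' Five-number velocity summaries by herd and season
#'
#' Boxplot-style summaries (median, quartiles, 1.5 IQR whiskers) of movement
#' velocity per herd-season cell. Empty cells are omitted with a warning.
#'
#' @param steps A step tibble with `herd`, `season`, `velocity`.
#' @return A tibble: `herd`, `season`, `n`, `whisker_low`, `q1`, `median`,
#'   `q3`, `whisker_high`.
#' @export
seasonal_velocity_summary <- function(steps) {
  d <- tibble::as_tibble(steps)
  stopifnot(all(c("herd", "season", "velocity") %in% names(d)))
  full <- tidyr::expand_grid(herd = unique(d$herd),
                             season = c("spring", "summer", "fall", "winter"))
  out <- d |>
    dplyr::group_by(.data$herd, .data$season) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$velocity, 0.25, names = FALSE),
      median = stats::median(.data$velocity),
      q3 = stats::quantile(.data$velocity, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      iqr = .data$q3 - .data$q1
    )
  wh <- purrr::map2_dfr(out$herd, out$season, function(h, s) {
    v <- d$velocity[d$herd == h & d$season == s]
    o <- out[out$herd == h & out$season == s, ]
    tibble::tibble(
      herd = h, season = s,
      whisker_low = min(v[v >= o$q1 - 1.5 * o$iqr]),
      whisker_high = max(v[v <= o$q3 + 1.5 * o$iqr])
    )
  })
  out <- dplyr::left_join(out, wh, by = c("herd", "season"))
  missing <- dplyr::anti_join(full, out, by = c("herd", "season"))
  if (nrow(missing)) {
    warning("seasonal_velocity_summary: ", nrow(missing),
            " empty herd-season cell(s) omitted")
  }
  out[, c("herd", "season", "n", "whisker_low", "q1", "median", "q3",
          "whisker_high")]
}
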