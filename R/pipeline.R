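#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one list (readable from
#' YAML via [read_pipeline_config()]): input paths or in-memory synthetic
#' recipes, LVE parameters, significance levels, sampling effort, season
#' calendar, and the output directory. `z_crit` defaults to the two-sided
#' normal quantile of `alpha`, keeping the trend and cluster stages at the
#' same nominal level.
#'
#' @param out_dir Output directory.
#' @param scene A [scene_recipe()] (synthetic mode), or `NULL` to read
#'   rasters from `stack_dir`/`mask_path`/`herds_path`.
#' @param tracks A [track_recipe()] (synthetic mode), or `NULL` to read
#'   telemetry from `telemetry_path`.
#' @param stack_dir,mask_path,herds_path,telemetry_path Input paths
#'   (file-based mode).
#' @param lve [lve_params()].
#' @param alpha Significance level for trend classification (default 0.05).
#' @param z_crit Critical z for cluster classification (default
#'   `qnorm(1 - alpha/2)`).
#' @param sample_n Stratified samples per herd (default 1000).
#' @param min_years Minimum valid years per pixel for the trend stage.
#' @param cal A [season_calendar()].
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scene = NULL, tracks = NULL,
                            stack_dir = NULL, mask_path = NULL,
                            herds_path = NULL, telemetry_path = NULL,
                            lve = lve_params(center_mode = "fixed"),
                            alpha = 0.05,
                            z_crit = stats::qnorm(1 - alpha / 2),
                            sample_n = 1000, min_years = 10,
                            cal = season_calendar(), seed = 1L) {
  if (is.null(scene) && (is.null(stack_dir) || is.null(mask_path) ||
                         is.null(herds_path))) {
    stop("pipeline_config: provide a scene recipe or stack_dir + mask_path",
         " + herds_path", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, scene = scene, tracks = tracks,
         stack_dir = stack_dir, mask_path = mask_path,
         herds_path = herds_path, telemetry_path = telemetry_path,
         lve = lve, alpha = alpha, z_crit = z_crit,
         sample_n = sample_n, min_years = min_years, cal = cal,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly; `lve:` maps to [lve_params()], `seasons:` to
#' [season_calendar()], `scene:`/`tracks:` to the synthetic recipes.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  lve <- if (is.null(y$lve)) lve_params(center_mode = "fixed")
         else do.call(lve_params, y$lve)
  cal <- if (is.null(y$seasons)) season_calendar()
         else do.call(season_calendar, lapply(y$seasons, unlist))
  scene <- if (is.null(y$scene)) NULL else {
    y$scene$params <- lve
    if (!is.null(y$scene$years)) y$scene$years <- do.call(seq, as.list(y$scene$years))
    if (!is.null(y$scene$clusters)) {
      y$scene$clusters <- dplyr::bind_rows(lapply(y$scene$clusters, tibble::as_tibble))
    }
    do.call(scene_recipe, y$scene)
  }
  tracks <- if (is.null(y$tracks)) NULL else {
    y$tracks$cal <- cal
    if (!is.null(y$tracks$years)) y$tracks$years <- do.call(seq, as.list(y$tracks$years))
    do.call(track_recipe, y$tracks)
  }
  args <- y[setdiff(names(y), c("lve", "seasons", "scene", "tracks"))]
  do.call(pipeline_config, c(args, list(lve = lve, cal = cal, scene = scene,
                                        tracks = tracks)))
}

write_csv_plain <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the raster chain (LVE, per-pixel trends, Gi* clusters, zonal
#' herd summaries, stratified sampling, spatial GLS with Tukey HSD) and,
#' when telemetry is configured, the movement chain (QC, step velocities,
#' LVE extraction, per-season velocity smooths). All artifacts are written
#' under `config$out_dir`, along with `manifest.json` recording inputs, a
#' configuration hash, seeds and the MD5 checksum of every output — the
#' manifest is a pure function of (inputs, config, seed), so identical runs
#' produce identical manifests. Stage timings and per-stage counters go to
#' `run_log.txt`, which is excluded from the manifest for that reason.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (list with `outputs`, `config_hash`,
#'   `seed`, ...).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  t_all <- proc.time()[3]
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, sprintf("[%6.1fs] %s", proc.time()[3] - t_all, msg))
    if (!quiet) message(msg)
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$scene)) {
    say("generating synthetic scene (seed %d)", config$scene$seed)
    scene <- make_scene(config$scene)
    stack <- scene$stack; mask <- scene$mask; ranges <- scene$ranges
    write_raster(scene$truth$slope, file.path(out, "true_slope.asc"))
  } else {
    say("reading stack from %s", config$stack_dir)
    stack <- read_stack(stack_files(config$stack_dir))
    mask_r <- read_raster(config$mask_path)
    mask <- lichen_mask(mask_r$grid, !is.na(mask_r$values) & mask_r$values > 0)
    if (!grids_aligned(mask$grid, stack$grid)) {
      mask <- resample_mask_nearest(mask, stack$grid)
    }
    ranges <- read_herd_ranges(config$herds_path)
  }

  # ---- raster chain -------------------------------------------------------
  say("scoring LVE for %d years", length(stack$years))
  lve <- lve_stack(stack, mask, config$lve)
  lve_dir <- file.path(out, "lve")
  dir.create(lve_dir, showWarnings = FALSE)
  for (y in names(lve)) {
    write_raster(lve[[y]], file.path(lve_dir, sprintf("lve_%s.asc", y)))
  }

  say("per-pixel Theil-Sen / Mann-Kendall trends (alpha %.3g)", config$alpha)
  tr <- trend_raster(lve, alpha = config$alpha, min_years = config$min_years)
  cls_code <- matrix(NA_real_, tr$grid$n_rows, tr$grid$n_cols)
  cls_code[tr$change_class == "increasing"] <- 1
  cls_code[tr$change_class == "decreasing"] <- -1
  cls_code[tr$change_class == "no_change"] <- 0
  write_raster(scalar_raster(tr$grid, tr$slope), file.path(out, "ts_slope.asc"))
  write_raster(scalar_raster(tr$grid, tr$mk_z), file.path(out, "mk_z.asc"))
  write_raster(scalar_raster(tr$grid, tr$p_value), file.path(out, "mk_p.asc"))
  write_raster(scalar_raster(tr$grid, cls_code), file.path(out, "trend_class.asc"))
  say("  classified %d pixels (%d invalid)", sum(!is.na(tr$change_class)),
      sum(is.na(tr$change_class)))

  say("Gi* clusters (z_crit %.3g)", config$z_crit)
  hs <- gi_star(slope_raster(tr), z_crit = config$z_crit)
  hs_code <- matrix(NA_real_, hs$grid$n_rows, hs$grid$n_cols)
  hs_code[hs$cluster_class == "positive_cluster"] <- 1
  hs_code[hs$cluster_class == "negative_cluster"] <- -1
  hs_code[hs$cluster_class == "no_cluster"] <- 0
  write_raster(scalar_raster(hs$grid, hs$gi_z), file.path(out, "gi_z.asc"))
  write_raster(scalar_raster(hs$grid, hs_code), file.path(out, "cluster_class.asc"))

  say("zonal summaries for %d herd(s)", length(herd_ids(ranges)))
  zon_tr <- zonal_class_percentages(tr, mask, ranges)
  zon_hs <- zonal_class_percentages(hs, mask, ranges)
  write_csv_plain(zon_tr, file.path(out, "zonal_trend.csv"))
  write_csv_plain(zon_hs, file.path(out, "zonal_cluster.csv"))

  say("stratified sampling (%d per herd) and spatial GLS", config$sample_n)
  samples <- stratified_sample(slope_raster(tr), ranges, n = config$sample_n,
                               seed = split_seed(config$seed, 20))
  gfit <- gls_herd_model(samples, correlation = "gaussian")
  tuk <- tukey_pairwise(gfit, alpha = config$alpha)
  write_csv_plain(samples, file.path(out, "slope_samples.csv"))
  write_csv_plain(glance(gfit), file.path(out, "gls_summary.csv"))
  write_csv_plain(gfit$group_means, file.path(out, "gls_group_means.csv"))
  write_csv_plain(tuk, file.path(out, "tukey_pairwise.csv"))
  say("  L.Ratio %.2f, herd F %.3f", gfit$lr_statistic, gfit$f_statistic)

  # ---- movement chain -----------------------------------------------------
  if (!is.null(config$tracks) || !is.null(config$telemetry_path)) {
    if (!is.null(config$tracks)) {
      say("simulating tracks (%d animals)", config$tracks$n_animals)
      fixes <- make_tracks(config$tracks, lve)
    } else {
      say("reading telemetry from %s", config$telemetry_path)
      fixes <- read_telemetry(config$telemetry_path)
    }
    fixes_qc <- qc_filter(fixes)
    dropped <- attr(fixes_qc, "dropped")
    say("  QC: %d of %d animals retained",
        length(unique(fixes_qc$animal_id)), length(unique(fixes$animal_id)))
    if (nrow(dropped)) {
      log_lines <- c(log_lines,
                     sprintf("    dropped %s: %s", dropped$animal_id,
                             dropped$reason))
    }
    steps <- step_velocities(fixes_qc, cal = config$cal)
    steps <- extract_lve_at_fixes(steps, lve)
    write_csv_plain(steps, file.path(out, "steps.csv"))
    write_csv_plain(seasonal_velocity_summary(steps),
                    file.path(out, "velocity_summary.csv"))

    fits <- list()
    for (s in c("spring", "summer", "fall", "winter")) {
      ss <- steps[steps$season == s & !is.na(steps$lve_at_start), ]
      fit <- tryCatch(fit_velocity_smooth(ss, season = s),
                      error = function(e) {
                        say("  season %s skipped: %s", s, conditionMessage(e))
                        NULL
                      })
      if (!is.null(fit)) {
        fits[[s]] <- fit
        write_csv_plain(predict_curve(fit),
                        file.path(out, sprintf("curve_%s.csv", s)))
      }
    }
    if (length(fits)) {
      write_csv_plain(dplyr::bind_rows(lapply(fits, glance)),
                      file.path(out, "association_summary.csv"))
    }
  }

  # ---- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.json", "run_log.txt")))
  sums <- tools::md5sum(file.path(out, files))
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file), add = TRUE)
  cfg_hashable <- config
  cfg_hashable$out_dir <- NULL  # output location is not scientific identity
  # closures serialize nondeterministically (environment frame order), so
  # the hash covers the parameter content only; every response function is
  # fully determined by its stored parameters
  strip_functions <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) x[] <- lapply(x, strip_functions)
    x
  }
  saveRDS(strip_functions(cfg_hashable), cfg_file, version = 2,
          compress = FALSE)
  manifest <- list(
    pipeline = "lichentrend",
    mode = if (is.null(config$scene)) "files" else "synthetic",
    seed = config$seed,
    alpha = config$alpha, z_crit = config$z_crit, sample_n = config$sample_n,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = lapply(seq_along(files),
                     function(i) list(path = files[i], md5 = unname(sums[i])))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d artifacts", length(files))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(manifest)
}
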