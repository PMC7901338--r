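# Experiment driver: runs the configured sweeps, writes every artifact
# under the output directory, and records them in a manifest keyed by the
# configuration hash.  All randomness derives from the configuration seed,
# so a manifest plus its configuration reproduces every file byte for
# byte.

#' Run a configured experiment
#'
#' For each requested window scheme, sweeps the configured modulation
#' periods into a spatiotemporal map (see [sweep_modulation_periods()]),
#' writing each map as CSV and PNG.  When several schemes are run and
#' `"conventional"` is among them, rolling-minus-conventional difference
#' maps are written as well.  A `manifest.json` lists every output file
#' together with the configuration and its hash.
#'
#' @param config An `experiment_config`.
#' @param metric `"rmse"` (default), `"dot"` or `"peak"`.
#' @param progress Emit per-period progress messages to standard error.
#' @return The manifest, invisibly: list with `config`, `config_hash`,
#'   `files`, and the `spatiotemporal_map` objects in `maps`.
#' @export
run_experiment <- function(config, metric = "rmse", progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out, ".write-probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", out,
                        call. = FALSE)
  unlink(probe)

  files <- character(0)
  maps <- list()
  cfg_path <- file.path(out, "config.yml")
  write_config(config, cfg_path)
  files <- c(files, cfg_path)

  for (scheme in config$schemes) {
    if (progress) message("scheme: ", scheme)
    map <- sweep_modulation_periods(config, metric = metric,
                                    scheme = scheme, progress = progress)
    maps[[scheme]] <- map
    csv <- file.path(out, sprintf("map_%s_%s.csv", metric, scheme))
    png <- file.path(out, sprintf("map_%s_%s.png", metric, scheme))
    write_map_csv(map, csv)
    save_map_png(map, png)
    files <- c(files, csv, png)
  }
  if ("conventional" %in% config$schemes) {
    for (scheme in setdiff(config$schemes, "conventional")) {
      dm <- difference_map(maps[[scheme]], maps[["conventional"]])
      key <- paste0(scheme, "_minus_conventional")
      csv <- file.path(out, sprintf("map_%s_%s.csv", metric, key))
      png <- file.path(out, sprintf("map_%s_%s.png", metric, key))
      write_map_csv(dm, csv)
      save_map_png(dm, png)
      files <- c(files, csv, png)
      maps[[key]] <- dm
    }
  }

  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   metric = metric, files = basename(files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$maps <- maps
  invisible(manifest)
}

#' Reproduce the package's four summary figures
#'
#' Runs the four canonical experiments at a chosen scale and writes one
#' figure each: (1) single-pixel temporal traces of one low and one high
#' spatial frequency against the ground-truth modulation, for a short, an
#' intermediate and a long modulation period; (2) the RMSE spatiotemporal
#' map; (3) a Poisson-noise panel (noisy minus noiseless RMSE map); (4)
#' rolling-minus-conventional difference maps.  The desk scale (default)
#' preserves the dimensionless ratios of the full-scale run (fringe period
#' / cutoff period = 1.1875; 16 windows) on a 128-pixel grid and completes
#' in minutes on one CPU.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param out_dir Output directory.
#' @param overrides Named list of [experiment_config()] arguments to
#'   override (e.g. a smaller grid for smoke tests).
#' @param progress Emit progress messages.
#' @return Manifest list (files written, configs used), invisibly.
#' @export
run_figure_suite <- function(scale = c("desk", "paper"),
                             out_dir = "simtempres-figures",
                             overrides = list(), progress = FALSE) {
  scale <- match.arg(scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_args <- utils::modifyList(list(scale = scale, out_dir = out_dir),
                                 overrides)
  cfg <- do.call(experiment_config, base_args)
  files <- character(0)

  window <- 9
  tm_short <- window
  tm_mid <- round(1.8 * window)
  tm_long <- max(cfg$periods)

  # shared machinery for the trace figure
  sample <- generate_point_sample(cfg$size, cfg$density, cfg$max_signal,
                                  seed = cfg$seed)
  otf <- make_otf(cfg$size, cfg$cutoff)
  patterns <- make_pattern_set(cfg$size, cfg$fringe_period, cfg$angles,
                               modulation_depth = cfg$modulation_depth)
  rc <- reconstruction_config("rolling1", wiener = cfg$wiener,
                              apodization = cfg$apodization)
  lim <- sim_passband_limit(cfg$cutoff, cfg$fringe_period, cfg$size)
  centre <- floor(cfg$size / 2) + 1
  low_px <- c(centre + round(cfg$cutoff / 8), centre)
  high_px <- c(centre + round((cfg$cutoff + lim) / 2), centre)

  fig1 <- file.path(out_dir, "fig_traces.png")
  grDevices::png(fig1, width = 1200, height = 900)
  graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  for (Tm in c(tm_short, tm_mid, tm_long)) {
    if (progress) message("trace figure, Tm = ", Tm)
    gt <- build_ground_truth_stack(sample, cfg$n_frames, Tm)
    raw <- acquire_raw_frames(gt, patterns, otf, noise_on = cfg$noise,
                              seed = cfg$seed)
    hr <- reconstruct_series(raw, otf, rc)
    sp <- spectrum_series(hr)
    times <- window_times(hr$window_start, cfg$registration)
    g <- normalize_trace(modulation_value(times, Tm))$values
    tl <- normalize_trace(sp$magnitudes[low_px[2], low_px[1], ])$values
    th <- normalize_trace(sp$magnitudes[high_px[2], high_px[1], ])$values
    graphics::matplot(times + 1, cbind(g, tl, th), type = "l", lty = 1,
                      col = c("black", "red", "orange"),
                      xlab = "frame", ylab = "z-scored intensity",
                      main = sprintf("Tm = %g frames", Tm))
    graphics::legend("topright", c("ground truth", "low fs", "high fs"),
                     col = c("black", "red", "orange"), lty = 1, cex = 0.8)
  }
  grDevices::dev.off()
  files <- c(files, fig1)

  # RMSE sweep map
  if (progress) message("RMSE sweep")
  cfg_rmse <- cfg
  map_r1 <- sweep_modulation_periods(cfg_rmse, scheme = "rolling1",
                                     progress = progress)
  fig2 <- file.path(out_dir, "fig_rmse_map.png")
  save_map_png(map_r1, fig2)
  write_map_csv(map_r1, file.path(out_dir, "map_rmse_rolling1.csv"))
  files <- c(files, fig2, file.path(out_dir, "map_rmse_rolling1.csv"))

  # noise sensitivity: noisy minus noiseless
  if (progress) message("noise panel")
  lvl <- if (!is.null(cfg$noise_levels)) cfg$noise_levels[1] else 10
  args_noisy <- utils::modifyList(
    base_args, list(noise = TRUE, max_signal = lvl))
  cfg_noisy <- do.call(experiment_config, args_noisy)
  map_noisy <- sweep_modulation_periods(cfg_noisy, scheme = "rolling1",
                                        progress = progress)
  dm_noise <- difference_map(map_noisy, map_r1)
  fig3 <- file.path(out_dir, "fig_noise.png")
  save_map_png(dm_noise, fig3,
               main = sprintf("noisy (max signal %g) - noiseless RMSE", lvl))
  files <- c(files, fig3)

  # rolling vs conventional differences
  if (progress) message("rolling comparison")
  map_conv <- sweep_modulation_periods(cfg, scheme = "conventional",
                                       progress = progress)
  map_r3 <- sweep_modulation_periods(cfg, scheme = "rolling3",
                                     progress = progress)
  fig4 <- file.path(out_dir, "fig_rolling_difference.png")
  grDevices::png(fig4, width = 1400, height = 700)
  graphics::par(mfrow = c(1, 2))
  plot(difference_map(map_r3, map_conv), main = "rolling-3 - conventional")
  plot(difference_map(map_r1, map_conv), main = "rolling-1 - conventional")
  grDevices::dev.off()
  files <- c(files, fig4)

  manifest <- list(scale = scale, config = unclass(cfg),
                   config_hash = config_hash(cfg), files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
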