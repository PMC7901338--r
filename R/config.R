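# Experiment configuration: one flat, YAML-serializable record of every
# knob in the pipeline, with two built-in scales (the full published-style
# run and a reduced desk run preserving the governing dimensionless
# ratios).

#' Experiment configuration
#'
#' Collects all simulation, acquisition, reconstruction and metric
#' settings.  The defaults are the desk scale: a 128-pixel grid with
#' cutoff 32 (cutoff period 4 px, as at full scale), fringe period 4.75 px
#' (fringe period / cutoff period = 1.1875, as at full scale) and 144
#' frames (16 nine-frame windows).  `experiment_config(scale = "paper")`
#' gives the full-scale settings: 512-pixel grid, cutoff 128, 512 frames,
#' periods 1..512.
#'
#' @param scale `"desk"` (default) or `"paper"`; sets the defaults below.
#' @param size Grid side length in pixels.
#' @param density Emitter density (fraction of pixels).
#' @param max_signal Emitter intensity in expected photons.
#' @param noise Apply Poisson noise?
#' @param noise_levels Optional vector of `max_signal` values for the
#'   noise-sensitivity experiment.
#' @param fringe_period Illumination fringe period in real-domain pixels.
#' @param cutoff OTF cutoff radius in frequency pixels.
#' @param angles Three pattern orientations in degrees.
#' @param modulation_depth Fringe modulation depth in (0, 1].
#' @param wiener Wiener regularization constant.
#' @param apodization `"triangle"` or `"none"`.
#' @param schemes Character vector of window schemes to run.
#' @param periods Modulation periods (frames) to sweep.
#' @param n_frames Number of raw frames per run.
#' @param seed Base integer seed (sample placement; per-period noise seeds
#'   are derived as `seed + period index`).
#' @param registration `"center"` (default) or `"start"` window-to-time
#'   rule for comparing reconstructions against the modulation.
#' @param out_dir Output directory for [run_experiment()].
#' @return An `experiment_config` object (a validated named list).
#' @export
experiment_config <- function(scale = c("desk", "paper"),
                              size = NULL, density = 0.01, max_signal = 1,
                              noise = FALSE, noise_levels = NULL,
                              fringe_period = 4.75, cutoff = NULL,
                              angles = c(0, 60, 120), modulation_depth = 1,
                              wiener = 0.05,
                              apodization = c("triangle", "none"),
                              schemes = "rolling1", periods = NULL,
                              n_frames = NULL, seed = 1L,
                              registration = c("center", "start"),
                              out_dir = "simtempres-out") {
  scale <- match.arg(scale)
  apodization <- match.arg(apodization)
  registration <- match.arg(registration)
  if (scale == "paper") {
    size <- size %||% 512L
    cutoff <- cutoff %||% 128
    n_frames <- n_frames %||% 512L
    periods <- periods %||% seq_len(512)
  } else {
    size <- size %||% 128L
    cutoff <- cutoff %||% 32
    n_frames <- n_frames %||% 144L
    periods <- periods %||% c(3, 4, 6, 8, 9, 12, 16, 18, 24, 36, 48, 72, 144)
  }
  bad <- setdiff(schemes, c("conventional", "rolling3", "rolling1"))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- list(
    scale = scale, size = as.integer(size), density = density,
    max_signal = max_signal, noise = isTRUE(noise),
    noise_levels = noise_levels, fringe_period = fringe_period,
    cutoff = cutoff, angles = angles, modulation_depth = modulation_depth,
    wiener = wiener, apodization = apodization, schemes = schemes,
    periods = as.numeric(periods), n_frames = as.integer(n_frames),
    seed = as.integer(seed), registration = registration,
    out_dir = out_dir)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    paste0("<experiment_config> %s scale: %d px grid, cutoff %g, fringe %g ",
           "px,\n  %d frames, %d periods, schemes %s, noise %s, seed %d\n"),
    x$scale, x$size, x$cutoff, x$fringe_period, x$n_frames,
    length(x$periods), paste(x$schemes, collapse = "/"),
    if (x$noise) "on" else "off", x$seed))
  invisible(x)
}

#' Write / read an experiment configuration as YAML
#'
#' The round trip `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config An `experiment_config`.
#' @param path File path for the YAML document.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}
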