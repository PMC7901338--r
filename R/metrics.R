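# Temporal-fidelity metrics: track each Fourier pixel's magnitude over the
# reconstructed series, z-score it, and compare against the known
# modulation with an RMSE (phase-sensitive) or a temporal power-spectrum
# dot product (phase-insensitive); collapse maps over annuli to profiles
# over spatial-frequency magnitude.

#' Fourier-magnitude time series of a reconstructed stack
#'
#' Computes the centered 2D Fourier transform magnitude of every frame in
#' a super-resolved stack.  Because the transform is linear, a uniform
#' temporal intensity modulation of the image imprints the same relative
#' modulation on every spatial frequency's magnitude, which is what the
#' downstream metrics score.
#'
#' @param hr An `hr_stack` (or any size x size x time array).
#' @return A `spectrum_series`: `magnitudes` (size x size x time array,
#'   centered layout), `size`, `n_frames`, plus `window_start` and
#'   `scheme` carried over when available.
#' @export
spectrum_series <- function(hr) {
  frames <- if (inherits(hr, "hr_stack")) hr$frames else hr
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  nt <- dim(frames)[3]
  if (nt < 1) stop("empty stack", call. = FALSE)
  mags <- array(0, dim = dim(frames))
  for (t in seq_len(nt)) {
    mags[, , t] <- Mod(fftshift2(fft2(frames[, , t])))
  }
  structure(
    list(magnitudes = mags, size = dim(frames)[1], n_frames = nt,
         window_start = if (inherits(hr, "hr_stack")) hr$window_start,
         scheme = if (inherits(hr, "hr_stack")) hr$scheme),
    class = "spectrum_series"
  )
}

# Population (divide-by-n) standard deviation; the z-score convention under
# which the RMSE bounds 0 and 2 are exact.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score a temporal trace
#'
#' Subtracts the mean and divides by the population standard deviation,
#' removing the arbitrary intensity scale so that traces from different
#' Fourier pixels (and the ground-truth modulation) are directly
#' comparable.
#'
#' @param trace Numeric time series, length >= 2.
#' @return A `normalized_trace`: `values` (mean 0, population sd 1),
#'   `mean`, `sd`.  A zero-variance trace raises a condition of class
#'   `simtempres_degenerate_trace`; map-level code catches it and marks the
#'   pixel invalid.
#' @export
normalize_trace <- function(trace) {
  if (inherits(trace, "normalized_trace")) return(trace)
  if (inherits(trace, "modulation_trace")) trace <- trace$values
  if (length(trace) < 2) stop("trace must have length >= 2", call. = FALSE)
  m <- mean(trace)
  s <- pop_sd(trace)
  if (s == 0 || !is.finite(s)) {
    stop(structure(
      class = c("simtempres_degenerate_trace", "error", "condition"),
      list(message = "degenerate trace: zero temporal variance",
           call = sys.call(-1))))
  }
  structure(list(values = (trace - m) / s, mean = m, sd = s),
            class = "normalized_trace")
}

trace_values <- function(x) {
  if (inherits(x, "normalized_trace")) x$values else normalize_trace(x)$values
}

#' Root-mean-square error between two z-scored traces
#'
#' `sqrt(mean((x - g)^2))` on z-scored operands.  The value is 0 for a
#' perfect reproduction of the ground-truth modulation, and can reach 2
#' when the modulation is reproduced in exact anti-phase; algebraically it
#' equals `sqrt(2 * (1 - rho))` where `rho` is the Pearson correlation of
#' the traces.  Two uncorrelated traces therefore score `sqrt(2)`, not 1 —
#' the operative "pure noise" floor of this metric (see the package
#' vignette).
#'
#' @param x,g Traces of equal length (`normalized_trace` objects, or
#'   numeric vectors which are z-scored first).
#' @return Non-negative scalar in `[0, 2]`.
#' @export
rmse_trace <- function(x, g) {
  xv <- trace_values(x); gv <- trace_values(g)
  if (length(xv) != length(gv)) stop("trace length mismatch", call. = FALSE)
  sqrt(mean((xv - gv)^2))
}

#' Phase-insensitive temporal power-spectrum dot product
#'
#' Inner product of the temporal power spectra of two z-scored traces,
#' `sum(|FFT(x)|^2 * |FFT(g)|^2)`.  Because the power spectrum discards
#' phase, a pure time lag between the traces does not change the value.
#' With `normalized = TRUE` (default) the product is divided by the
#' Euclidean norms of the two power spectra, giving 1 for identical (or
#' anti-phase) traces and 0 for traces whose power lives in disjoint
#' frequency bins.
#'
#' @param x,g Traces of equal length (z-scored internally if needed).
#' @param normalized Scale into `[0, 1]` by the power-spectrum norms.
#' @return Non-negative scalar.
#' @export
dot_metric <- function(x, g, normalized = TRUE) {
  xv <- trace_values(x); gv <- trace_values(g)
  if (length(xv) != length(gv)) stop("trace length mismatch", call. = FALSE)
  px <- Mod(stats::fft(xv))^2
  pg <- Mod(stats::fft(gv))^2
  v <- sum(px * pg)
  if (normalized) v <- v / (sqrt(sum(px^2)) * sqrt(sum(pg^2)))
  v
}

#' Fraction of a trace's temporal power at the modulation frequency
#'
#' Single-bin alternative to [dot_metric()]: the share of a z-scored
#' trace's temporal variance concentrated in the Fourier bin of the
#' ground-truth oscillation (`n_cycles` full periods over the trace).
#' 1 means a pure sinusoid at the modulation frequency; values near 0 mean
#' the modulation is lost.
#'
#' @param x Trace (z-scored internally if needed).
#' @param n_cycles Number of modulation periods spanned by the trace
#'   (integer >= 1; meaningful when the period divides the trace length).
#' @return Scalar in `[0, 1]`.
#' @export
temporal_peak_magnitude <- function(x, n_cycles) {
  xv <- trace_values(x)
  nt <- length(xv)
  if (n_cycles < 1 || n_cycles > nt / 2) {
    stop("`n_cycles` must be in [1, length/2]", call. = FALSE)
  }
  p <- Mod(stats::fft(xv))^2
  2 * p[n_cycles + 1] / sum(p)   # +/- frequency bins are mirror images
}

# Ground-truth modulation sampled at the reconstruction window times.
window_times <- function(window_start, registration = c("center", "start")) {
  registration <- match.arg(registration)
  if (registration == "start") window_start else window_start + 4
}

#' Per-spatial-frequency temporal error map
#'
#' For every Fourier pixel of a reconstructed series, z-scores its
#' magnitude trace and computes the RMSE against the z-scored ground-truth
#' modulation evaluated at the window times.  Pixels whose trace has zero
#' temporal variance, or variance below `1e-12` of the series' peak
#' magnitude (the numerical floor of the double-precision transforms, e.g.
#' frequencies zeroed by apodization), are marked invalid (`NA`) and
#' excluded from radial averages.
#'
#' @param spectra A `spectrum_series` carrying `window_start`.
#' @param Tm Ground-truth modulation period in raw frames.
#' @param registration How a window maps to a ground-truth time:
#'   `"center"` (default) evaluates the modulation at the window's middle
#'   raw frame, `"start"` at its first frame.  Center registration removes
#'   the half-window lag common to all spatial frequencies, so the metric
#'   isolates the *differential* phase lag of high spatial frequencies;
#'   start registration keeps the common lag in the score.
#' @param metric `"rmse"` (default), `"dot"` (normalized power-spectrum dot
#'   product) or `"peak"` (single-bin power fraction; requires `Tm` to
#'   divide the series length times the stride evenly to be meaningful).
#' @return An `st_error_map`: `values` (centered size x size matrix, `NA`
#'   for invalid pixels), `metric`, `Tm`, `nt`, `n_degenerate`, `size`.
#' @export
rmse_map <- function(spectra, Tm, registration = c("center", "start"),
                     metric = c("rmse", "dot", "peak")) {
  stopifnot(inherits(spectra, "spectrum_series"))
  metric <- match.arg(metric)
  registration <- match.arg(registration)
  if (is.null(spectra$window_start)) {
    stop("`spectra` does not carry window start times", call. = FALSE)
  }
  times <- window_times(spectra$window_start, registration)
  g <- modulation_value(times, Tm)
  nt <- length(times)
  n <- spectra$size
  X <- matrix(spectra$magnitudes, n * n, nt)   # rows: pixels, cols: time
  mu <- rowMeans(X)
  sd <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  # numerical floor: a pixel fluctuating below 1e-12 of the series peak is
  # double-precision residue (e.g. apodized-out frequencies), not signal
  valid <- sd > 1e-12 * max(X)
  gs <- pop_sd(g)
  if (gs == 0) {
    stop("ground-truth trace is constant at the sampled window times ",
         "(Tm divides the window stride); choose a different Tm or scheme",
         call. = FALSE)
  }
  gz <- (g - mean(g)) / gs
  vals <- rep(NA_real_, n * n)
  if (any(valid)) {
    Z <- (X[valid, , drop = FALSE] - mu[valid]) / sd[valid]
    if (metric == "rmse") {
      # sqrt(mean((z - g)^2)) = sqrt(2 * (1 - rho)) for z-scored operands
      rho <- as.vector(Z %*% gz) / nt
      vals[valid] <- sqrt(pmax(2 * (1 - rho), 0))
    } else if (metric == "dot") {
      PG <- Mod(stats::fft(gz))^2
      vals[valid] <- apply(Z, 1L, function(z) {
        pz <- Mod(stats::fft(z))^2
        sum(pz * PG) / (sqrt(sum(pz^2)) * sqrt(sum(PG^2)))
      })
    } else {
      strides <- diff(times)
      stride <- if (length(strides)) strides[1] else 1
      n_cycles <- round(nt * stride / Tm)
      if (n_cycles < 1 || n_cycles > nt / 2) {
        stop("modulation period incompatible with single-bin extraction",
             call. = FALSE)
      }
      vals[valid] <- apply(Z, 1L, function(z) {
        p <- Mod(stats::fft(z))^2
        2 * p[n_cycles + 1] / sum(p)
      })
    }
  }
  structure(
    list(values = matrix(vals, n, n), metric = metric, Tm = Tm, nt = nt,
         n_degenerate = sum(!valid), size = n,
         registration = registration),
    class = "st_error_map"
  )
}

#' @export
print.st_error_map <- function(x, ...) {
  cat(sprintf(
    "<st_error_map> %s, Tm = %g, %d timepoints, %d degenerate px\n",
    x$metric, x$Tm, x$nt, x$n_degenerate))
  invisible(x)
}

#' Radially average a Fourier-plane map
#'
#' Averages map values over annuli: bin `r` collects all pixels whose
#' distance from DC satisfies `floor(distance) == r`, for `r` from 0 to
#' `N/2 - 1` (DC alone in bin 0; pixels at or beyond the Nyquist radius
#' are not binned).  Invalid (`NA`) pixels are excluded from the mean but
#' counted in the annulus cardinality; a bin with no valid pixel is
#' reported as `NA`, never as zero.
#'
#' @param map An `st_error_map`, or a plain centered square matrix (with
#'   `NA` marking invalid pixels).
#' @return A `radial_profile` data frame: `radius` (bin lower edge),
#'   `value` (mean over valid pixels), `count` (annulus cardinality),
#'   `n_valid`.
#' @export
radial_average <- function(map) {
  values <- if (inherits(map, "st_error_map")) map$values else map
  stopifnot(is_square_matrix(values))
  n <- nrow(values)
  r <- floor(centered_radius(n))
  keep <- r < n / 2
  bin <- factor(r[keep], levels = 0:(n / 2 - 1))
  v <- values[keep]
  count <- as.integer(table(bin))
  n_valid <- as.integer(tapply(!is.na(v), bin, sum, default = 0L))
  value <- as.numeric(tapply(v, bin, mean, na.rm = TRUE, default = NA_real_))
  value[n_valid == 0L] <- NA_real_
  out <- data.frame(radius = 0:(n / 2 - 1), value = value, count = count,
                    n_valid = n_valid)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Sweep modulation periods into a spatial-frequency x period map
#'
#' Runs the full pipeline (modulated ground truth, structured acquisition,
#' windowed reconstruction, per-pixel temporal metric, radial average) for
#' each modulation period in a configuration, and stacks the radial
#' profiles into a matrix of radial bin x period.  The point sample is
#' drawn once from the run seed and reused for every period.  For the
#' `"dot"` and `"peak"` metrics the period list is restricted to even
#' integer divisors of `n_frames`, so the ground-truth power concentrates
#' in single temporal-frequency bins.
#'
#' A period whose pipeline fails (e.g. the sampled ground-truth trace is
#' constant under the window stride) is recorded as a missing column and
#' reported in a message, not an error.
#'
#' @param config An `experiment_config` (see [experiment_config()]);
#'   `config$schemes[1]` is the scheme swept.
#' @param metric `"rmse"` (default), `"dot"` or `"peak"`.
#' @param scheme Optional scheme override (`"conventional"`, `"rolling3"`,
#'   `"rolling1"`).
#' @param progress Emit a message per period (default `FALSE`).
#' @return A `spatiotemporal_map`: `matrix` (radial bins x periods),
#'   `periods`, `radii`, `metric`, `scheme`, `meta` (the configuration
#'   used), `failed` (periods whose column is missing).
#' @export
sweep_modulation_periods <- function(config, metric = c("rmse", "dot", "peak"),
                                     scheme = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  metric <- match.arg(metric)
  scheme <- scheme %||% config$schemes[1]
  periods <- config$periods
  if (metric %in% c("dot", "peak")) {
    keep <- periods %% 2 == 0 & config$n_frames %% periods == 0
    periods <- periods[keep]
  }
  if (length(periods) == 0) stop("empty period list", call. = FALSE)
  sample <- generate_point_sample(config$size, config$density,
                                  config$max_signal, seed = config$seed)
  otf <- make_otf(config$size, config$cutoff)
  patterns <- make_pattern_set(config$size, config$fringe_period,
                               config$angles,
                               modulation_depth = config$modulation_depth)
  rc <- reconstruction_config(scheme, wiener = config$wiener,
                              apodization = config$apodization)
  n_bins <- config$size / 2
  mat <- matrix(NA_real_, n_bins, length(periods))
  failed <- logical(length(periods))
  for (i in seq_along(periods)) {
    Tm <- periods[i]
    if (progress) message(sprintf("Tm = %g (%d/%d)", Tm, i, length(periods)))
    res <- tryCatch({
      gt <- build_ground_truth_stack(sample, config$n_frames, Tm)
      raw <- acquire_raw_frames(gt, patterns, otf,
                                noise_on = isTRUE(config$noise),
                                seed = config$seed + i)
      hr <- reconstruct_series(raw, otf, rc)
      emap <- rmse_map(spectrum_series(hr), Tm,
                       registration = config$registration, metric = metric)
      radial_average(emap)$value
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      message(sprintf("period Tm = %g skipped: %s", Tm, conditionMessage(res)))
    } else {
      mat[, i] <- res
    }
  }
  structure(
    list(matrix = mat, periods = periods, radii = 0:(n_bins - 1),
         metric = metric, scheme = scheme, meta = config,
         failed = periods[failed]),
    class = "spatiotemporal_map"
  )
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat(sprintf(
    "<spatiotemporal_map> %s / %s: %d radial bins x %d periods%s\n",
    x$metric, x$scheme, length(x$radii), length(x$periods),
    if (length(x$failed)) sprintf(" (%d missing)", length(x$failed)) else ""))
  invisible(x)
}

#' Difference between two spatiotemporal maps
#'
#' Elementwise `a - b` (e.g. rolling minus conventional, the degradation
#' map of a rolling scheme).  Axes must match; missing cells propagate.
#'
#' @param a,b `spatiotemporal_map` objects on identical period and radius
#'   axes and the same metric.
#' @return A `spatiotemporal_map` with `scheme` set to `"a-b"` labels.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "spatiotemporal_map"),
            inherits(b, "spatiotemporal_map"))
  if (!identical(a$periods, b$periods) || !identical(a$radii, b$radii) ||
      !identical(a$metric, b$metric)) {
    stop("maps must share period axis, radius axis and metric",
         call. = FALSE)
  }
  out <- a
  out$matrix <- a$matrix - b$matrix
  out$scheme <- paste0(a$scheme, "-", b$scheme)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
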