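#' Generate a sparse point-emitter sample
#'
#' Creates the simulation ground truth: a square image in which a fixed
#' fraction of pixels (drawn without replacement) is set to `max_signal`
#' photons and all remaining pixels are zero.  Sparse point emitters give
#' the sample spectral support at every spatial frequency, which is what
#' lets the temporal-fidelity metrics interrogate the full Fourier plane.
#'
#' The emitter count is exact: `round(density * size^2)` pixels are chosen,
#' so repeated runs differ only in emitter positions, never in number.
#'
#' @param size Image side length in pixels (`size >= 16`).
#' @param density Fraction of pixels that hold an emitter, in `[0, 1]`.
#'   The default 0.01 places emitters in 1% of pixels.
#' @param max_signal Emitter intensity in expected photons (`> 0`).  Kept at
#'   1 for noise-free runs; raised for Poisson-noise experiments.
#' @param seed Integer seed controlling emitter placement.  The global RNG
#'   state is left untouched.
#' @return A `sample_image` object: list with `pixels` (size x size matrix),
#'   `size`, `density`, `max_signal`, `n_emitters`, `seed`.
#' @examples
#' s <- generate_point_sample(64, 0.01, 1, seed = 1)
#' sum(s$pixels > 0)  # exactly round(0.01 * 64^2) = 41
#' @export
generate_point_sample <- function(size, density = 0.01, max_signal = 1,
                                  seed = 1L) {
  if (length(size) != 1L || !is.finite(size) || size < 16 ||
      size != round(size)) {
    stop("`size` must be a single integer >= 16", call. = FALSE)
  }
  if (density < 0 || density > 1) {
    stop("`density` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(max_signal) || max_signal <= 0) {
    stop("`max_signal` must be positive", call. = FALSE)
  }
  n_px <- as.integer(size)^2
  n_on <- as.integer(round(density * n_px))
  px <- matrix(0, size, size)
  if (n_on > 0) {
    idx <- withr::with_seed(seed, sample.int(n_px, n_on, replace = FALSE))
    px[idx] <- max_signal
  }
  structure(
    list(pixels = px, size = as.integer(size), density = density,
         max_signal = max_signal, n_emitters = n_on, seed = seed),
    class = "sample_image"
  )
}

#' @export
print.sample_image <- function(x, ...) {
  cat(sprintf("<sample_image> %d x %d px, %d emitters at %g photons\n",
              x$size, x$size, x$n_emitters, x$max_signal))
  invisible(x)
}

#' Ground-truth temporal modulation
#'
#' The known laser-intensity modulation applied to the sample:
#' `0.75 + sin(2*pi*t / Tm) / 4`, which oscillates between 0.5 and 1.
#' The lower bound of 0.5 (rather than 0) avoids frames with vanishing
#' intensity, which would create reconstruction artefacts unrelated to
#' temporal resolution.
#'
#' @param t Frame index (0-based; may be a vector, need not be integer).
#' @param Tm Modulation period in frames (`> 0`).
#' @return Dimensionless modulation factor(s) in `[0.5, 1]`.
#' @examples
#' modulation_value(0, 16)   # 0.75
#' modulation_value(4, 16)   # 1.0 (quarter period)
#' @export
modulation_value <- function(t, Tm) {
  if (length(Tm) != 1L || !is.finite(Tm) || Tm <= 0) {
    stop("`Tm` must be a single positive number", call. = FALSE)
  }
  0.75 + sin(2 * pi * t / Tm) / 4
}

#' Build a modulation trace over a frame range
#'
#' @param Tm Modulation period in frames.
#' @param n_frames Number of frames; values are evaluated at t = 0 ..
#'   n_frames - 1.
#' @return A `modulation_trace` object with `Tm`, `n_frames` and `values`.
#' @export
modulation_trace <- function(Tm, n_frames) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  structure(
    list(Tm = Tm, n_frames = as.integer(n_frames),
         values = modulation_value(seq_len(n_frames) - 1, Tm)),
    class = "modulation_trace"
  )
}

#' @export
print.modulation_trace <- function(x, ...) {
  cat(sprintf("<modulation_trace> Tm = %g frames, %d frames, range [%g, %g]\n",
              x$Tm, x$n_frames, min(x$values), max(x$values)))
  invisible(x)
}

#' Build the temporally modulated ground-truth stack
#'
#' Frame `t` is the sample image scaled by the modulation factor
#' `modulation_value(t, Tm)`; no noise or blurring is applied at this
#' stage.  The per-frame mean intensity therefore follows the modulation
#' exactly, with a max/min ratio of 2 over a full period.
#'
#' @param sample A `sample_image` (or a plain non-negative square matrix).
#' @param n_frames Number of timepoints (`>= 9`, one full pattern cycle).
#' @param Tm Modulation period in frames.
#' @return A `ground_truth_stack`: list with `frames` (size x size x
#'   n_frames array), `trace` (the `modulation_trace` used), `n_frames`,
#'   `size`.
#' @export
build_ground_truth_stack <- function(sample, n_frames, Tm) {
  px <- if (inherits(sample, "sample_image")) sample$pixels else sample
  if (!is_square_matrix(px)) stop("`sample` must be square", call. = FALSE)
  if (n_frames < 9) {
    stop("`n_frames` must be >= 9: at least one 9-frame pattern cycle is ",
         "needed for reconstruction", call. = FALSE)
  }
  tr <- modulation_trace(Tm, n_frames)
  n <- nrow(px)
  frames <- array(as.vector(px), dim = c(n, n, n_frames)) *
    rep(tr$values, each = n * n)
  structure(
    list(frames = frames, trace = tr, n_frames = as.integer(n_frames),
         size = n),
    class = "ground_truth_stack"
  )
}

#' @export
print.ground_truth_stack <- function(x, ...) {
  cat(sprintf("<ground_truth_stack> %d frames of %d x %d px, Tm = %g\n",
              x$n_frames, x$size, x$size, x$trace$Tm))
  invisible(x)
}
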