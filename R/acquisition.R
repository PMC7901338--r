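# Structured-illumination acquisition: the nine-pattern fringe sequence,
# image formation through the OTF, and Poisson shot noise.

#' Build the nine-pattern illumination sequence
#'
#' Generates the 3 angles x 3 phases sinusoidal illumination masks,
#' `1 + m * cos(2*pi * (k.r) / fringe_period + phase)`, in angle-major
#' order: patterns 1-3 share the first angle with phases 0, 2pi/3, 4pi/3,
#' patterns 4-6 the second angle, patterns 7-9 the third.  Each mask has
#' unit mean (up to grid discretization of the non-integer fringe
#' frequency), so the illumination dose matches widefield, and the three
#' phase masks at one angle sum pointwise to the constant 3.
#'
#' The masks model the excitation path and are not blurred by the
#' detection OTF; the fringe period (default 4.75 px) is chosen just above
#' the OTF cutoff period so fringes of this period are physically
#' transmissible.  The fringe frequency `size / fringe_period` need not be
#' an integer; masks are evaluated analytically per pixel, with no snapping
#' to grid frequencies.
#'
#' @param size Grid side length in pixels.
#' @param fringe_period Fringe period in real-domain pixels (`> 2`).
#' @param angles Three pattern orientations in degrees.  Defaults to 0, 60,
#'   120 (equally spaced, the standard choice for isotropic coverage).
#' @param phases Three phase offsets in radians, default 0, 2pi/3, 4pi/3.
#' @param modulation_depth Fringe modulation depth `m` in (0, 1]; default 1.
#' @return A `pattern_set` object: `patterns` (size x size x 9 array),
#'   `angles`, `phases`, `fringe_period`, `modulation_depth`, `kvec`
#'   (3 x 2 matrix of fringe wave-vectors in frequency pixels, x and y
#'   components per angle), `size`.
#' @export
make_pattern_set <- function(size, fringe_period = 4.75,
                             angles = c(0, 60, 120),
                             phases = c(0, 2 * pi / 3, 4 * pi / 3),
                             modulation_depth = 1) {
  if (fringe_period <= 2) {
    stop("fringe frequency at or above Nyquist: `fringe_period` must be > 2",
         call. = FALSE)
  }
  if (length(angles) != 3L || length(phases) != 3L) {
    stop("exactly 3 angles and 3 phases are required", call. = FALSE)
  }
  m <- modulation_depth
  if (m < 0 || m > 1) stop("`modulation_depth` must be in [0, 1]",
                           call. = FALSE)
  n <- as.integer(size)
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  theta <- angles * pi / 180
  kvec <- cbind(x = (n / fringe_period) * cos(theta),
                y = (n / fringe_period) * sin(theta))
  patterns <- array(0, dim = c(n, n, 9L))
  for (a in 1:3) {
    proj <- 2 * pi * (cos(theta[a]) * x + sin(theta[a]) * y) / fringe_period
    for (p in 1:3) {
      patterns[, , 3 * (a - 1) + p] <- 1 + m * cos(proj + phases[p])
    }
  }
  structure(
    list(patterns = patterns, angles = angles, phases = phases,
         fringe_period = fringe_period, modulation_depth = m,
         kvec = kvec, size = n),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf(
    "<pattern_set> 9 masks, %d px, fringe period %g px, m = %g,\n  angles %s deg\n",
    x$size, x$fringe_period, x$modulation_depth,
    paste(signif(x$angles, 4), collapse = "/")))
  invisible(x)
}

#' Draw Poisson shot noise
#'
#' Replaces each pixel by an independent Poisson draw whose mean is the
#' pixel value, modelling photon shot noise (camera read noise and gain
#' excluded).  Input pixels must be non-negative expected photon counts.
#'
#' @param image Non-negative matrix of expected photons.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Integer-valued matrix of photon counts.
#' @export
add_poisson <- function(image, seed = 1L) {
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("Poisson input must be finite and non-negative", call. = FALSE)
  }
  counts <- withr::with_seed(seed, stats::rpois(length(image), image))
  matrix(as.numeric(counts), nrow(image), ncol(image))
}

#' Acquire raw SIM frames from a ground-truth stack
#'
#' Forms the raw data exactly in the physical order: temporal modulation
#' (already in the ground truth), multiplication by the cycling
#' illumination mask (frame `t` uses pattern `t mod 9`), blurring by the
#' detection OTF, then (optionally) Poisson noise on the blurred image.
#'
#' The blurred image is mathematically non-negative (the PSF is the squared
#' modulus of the aperture amplitude); float round-off can leave residue on
#' the order of machine epsilon below zero, which is snapped to exact zero
#' before the Poisson draw.  Anything more negative than `1e-9` of the
#' frame peak indicates a corrupted input and raises an error.
#'
#' @param gt A `ground_truth_stack`.
#' @param patterns A `pattern_set` on the same grid.
#' @param otf An `otf_model` on the same grid.
#' @param noise_on Apply Poisson noise? Default `FALSE`.
#' @param seed Integer seed for the noise draws (one stream across the
#'   whole stack, so frames are independent).
#' @return A `raw_frame_stack`: `frames` (size x size x n array),
#'   `pattern_index` (0-based, `t mod 9` per frame), `noise_applied`,
#'   `seed`, `n_frames`, `size`, and the acquisition metadata (`angles`,
#'   `phases`, `fringe_period`, `modulation_depth`, `kvec`, `cutoff`).
#' @export
acquire_raw_frames <- function(gt, patterns, otf, noise_on = FALSE,
                               seed = 1L) {
  stopifnot(inherits(gt, "ground_truth_stack"),
            inherits(patterns, "pattern_set"),
            inherits(otf, "otf_model"))
  if (gt$size != patterns$size || gt$size != otf$size) {
    stop("ground truth, patterns and OTF must share the grid size",
         call. = FALSE)
  }
  n <- gt$size
  nt <- gt$n_frames
  otf_native <- ifftshift2(otf$transfer)
  frames <- array(0, dim = c(n, n, nt))
  for (t in seq_len(nt)) {
    p_idx <- (t - 1) %% 9
    img <- Re(ifft2(fft2(gt$frames[, , t] * patterns$patterns[, , p_idx + 1]) *
                      otf_native))
    peak <- max(img, 0)
    if (min(img) < -1e-9 * max(peak, 1)) {
      stop("negative intensity entering the Poisson step: blurred frame ",
           t, " has min ", min(img), call. = FALSE)
    }
    img[img < 0] <- 0
    frames[, , t] <- img
  }
  if (noise_on) {
    counts <- withr::with_seed(seed, stats::rpois(length(frames), frames))
    frames <- array(as.numeric(counts), dim = dim(frames))
  }
  structure(
    list(frames = frames, pattern_index = (seq_len(nt) - 1L) %% 9L,
         noise_applied = isTRUE(noise_on), seed = seed,
         n_frames = nt, size = n,
         angles = patterns$angles, phases = patterns$phases,
         fringe_period = patterns$fringe_period,
         modulation_depth = patterns$modulation_depth,
         kvec = patterns$kvec, cutoff = otf$cutoff),
    class = "raw_frame_stack"
  )
}

#' @export
print.raw_frame_stack <- function(x, ...) {
  cat(sprintf("<raw_frame_stack> %d frames of %d x %d px, noise %s\n",
              x$n_frames, x$size, x$size,
              if (x$noise_applied) "on" else "off"))
  invisible(x)
}
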