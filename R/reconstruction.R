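# Gustafsson-style SIM reconstruction: per-angle phase separation, sub-pixel
# spectral shifting by the fringe wave-vector, and a generalized Wiener
# merge with apodization, scheduled over conventional or rolling windows.
#
# Forward model (per angle, phase j, native FFT layout):
#   D_j(f) = OTF(f) * [ S(f) + (m/2) e^{+i phi_j} S(f - k) +
#                              (m/2) e^{-i phi_j} S(f + k) ]
# so the separation solves, per Fourier pixel, the 3x3 system with mixing
# row (1, (m/2) e^{+i phi_j}, (m/2) e^{-i phi_j}).

#' Reconstruction configuration
#'
#' Bundles the window scheme and the spectral-merge settings.  The pattern
#' parameters (angles, phases, fringe wave-vectors, modulation depth) are
#' taken as known from the acquisition metadata: this simulator controls
#' the illumination exactly, so no parameter estimation from data is
#' performed.
#'
#' @param scheme Window schedule: `"conventional"` (stride 9, disjoint
#'   windows), `"rolling3"` (stride 3, windows keep whole same-angle phase
#'   triples), or `"rolling1"` (stride 1, a new reconstruction every frame;
#'   in two thirds of windows one phase triple is split between the ends of
#'   the window).
#' @param wiener Wiener regularization constant (> 0), default 0.05.
#' @param apodization `"triangle"` (default; falls linearly to zero at the
#'   extended pass-band radius) or `"none"` (diagnostics only).
#' @param mean_normalize Equalize each window's reconstructed mean
#'   brightness to that of the first window.  Off by default: the default
#'   pipeline is linear in the input intensity, which the temporal metrics
#'   rely on.  Turning it on reproduces the normalization mechanism that
#'   can distort interleaved rolling reconstructions.
#' @return A `reconstruction_config` object.
#' @export
reconstruction_config <- function(scheme = c("conventional", "rolling3",
                                             "rolling1"),
                                  wiener = 0.05,
                                  apodization = c("triangle", "none"),
                                  mean_normalize = FALSE) {
  scheme <- match.arg(scheme)
  apodization <- match.arg(apodization)
  if (!is.finite(wiener) || wiener <= 0) {
    stop("`wiener` must be positive", call. = FALSE)
  }
  stride <- c(conventional = 9L, rolling3 = 3L, rolling1 = 1L)[[scheme]]
  structure(list(scheme = scheme, stride = stride, wiener = wiener,
                 apodization = apodization,
                 mean_normalize = isTRUE(mean_normalize)),
            class = "reconstruction_config")
}

#' Window start indices for a reconstruction scheme
#'
#' 0-based raw-frame indices at which each 9-frame reconstruction window
#' begins: stride 9 for conventional, 3 for rolling-3, 1 for rolling-1.
#' On 512 raw frames this gives 56, 168 and 504 windows respectively.
#'
#' @param n_raw Number of raw frames (>= 9).
#' @param scheme `"conventional"`, `"rolling3"` or `"rolling1"`.
#' @return Integer vector of 0-based window starts.
#' @export
window_starts <- function(n_raw, scheme = c("conventional", "rolling3",
                                            "rolling1")) {
  scheme <- match.arg(scheme)
  if (n_raw < 9) stop("need at least 9 raw frames", call. = FALSE)
  stride <- c(conventional = 9L, rolling3 = 3L, rolling1 = 1L)[[scheme]]
  seq.int(0L, n_raw - 9L, by = stride)
}

#' Separate the three spectral components at one angle
#'
#' Per Fourier pixel, inverts the 3x3 phase-mixing system relating the
#' three observed phase-shifted frames to the unshifted component and the
#' two fringe-shifted components.  The returned spectra are still weighted
#' by the OTF at the observation frequency; [shift_component()] moves the
#' side components to their true frequency positions.
#'
#' @param frames List (or array slice) of the 3 real-domain frames acquired
#'   at one angle, ordered to match `phases`.
#' @param phases The 3 pattern phases in radians (distinct modulo 2pi).
#' @param m Modulation depth used in the acquisition.
#' @return List of 3 complex spectra (native FFT layout): `center`, `plus`
#'   (content shifted up by +k), `minus` (content shifted by -k).
#' @export
separate_components <- function(frames, phases, m = 1) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  stopifnot(length(frames) == 3L, length(phases) == 3L)
  spectra <- lapply(frames, fft2)
  separate_from_spectra(spectra, phase_mixing_inverse(phases, m))
}

# Inverse of the 3x3 mixing matrix; errors on (near-)degenerate phases.
phase_mixing_inverse <- function(phases, m) {
  M <- cbind(1, (m / 2) * exp(1i * phases), (m / 2) * exp(-1i * phases))
  d <- svd(M)$d
  if (m == 0 || d[3] < 1e-10 * d[1]) {
    stop("ill-conditioned phase-mixing matrix: phases must be distinct ",
         "modulo 2*pi and m > 0", call. = FALSE)
  }
  solve(M)
}

separate_from_spectra <- function(spectra, Minv) {
  n <- nrow(spectra[[1]])
  D <- rbind(as.vector(spectra[[1]]), as.vector(spectra[[2]]),
             as.vector(spectra[[3]]))
  C <- Minv %*% D
  list(center = matrix(C[1, ], n, n),
       plus   = matrix(C[2, ], n, n),
       minus  = matrix(C[3, ], n, n))
}

#' Translate a spectrum by a (sub-pixel) frequency-space vector
#'
#' Returns the spectrum `G` with `G(f) = F(f - shift)`, implemented through
#' the Fourier shift theorem: inverse-transform, multiply by a complex
#' exponential ramp, forward-transform.  The shift may be fractional (the
#' fringe frequency `size / 4.75` is not an integer) and is circular
#' (content wraps around the Nyquist boundary).
#'
#' @param spectrum Complex matrix in native FFT layout.
#' @param shift Length-2 numeric, (x, y) components of the translation in
#'   frequency pixels; magnitude must stay below the Nyquist radius.
#' @return Complex matrix, same layout.
#' @export
shift_component <- function(spectrum, shift) {
  n <- nrow(spectrum)
  if (sqrt(sum(shift^2)) >= n / 2) {
    stop("|shift| must be below the Nyquist radius", call. = FALSE)
  }
  if (all(shift == 0)) return(spectrum)
  x <- 0:(n - 1)
  ramp <- exp(2i * pi * outer(shift[2] * x, shift[1] * x, "+") / n)
  fft2(ifft2(spectrum) * ramp)
}

# Precomputed per-configuration machinery: shifted-OTF weights for the 7
# distinct component positions (center + two per angle), the Wiener
# denominator, and the apodization window, all as native-layout matrices.
make_reconstruction_plan <- function(raw, otf, config) {
  n <- raw$size
  cutoff <- otf$cutoff
  shifts <- vector("list", 7L)
  shifts[[1]] <- c(0, 0)                       # center component
  for (a in 1:3) {
    k <- raw$kvec[a, ]
    shifts[[2 * a]]     <- -k                  # applied to `plus`
    shifts[[2 * a + 1]] <- +k                  # applied to `minus`
  }
  # component shifted by v carries OTF(|q - v|): OTF support follows the
  # translation
  weights <- lapply(shifts, function(v) {
    otf_radial(native_shifted_radius(n, v) / cutoff)
  })
  denom <- Reduce(`+`, lapply(weights, function(w) w^2))
  # the center component is measured three times (once per angle)
  denom <- denom + 2 * weights[[1]]^2 + config$wiener^2
  apod_radius <- sim_passband_radius(cutoff, raw$fringe_period, n)
  apod <- if (config$apodization == "triangle") {
    ifftshift2(matrix(pmax(0, 1 - centered_radius(n) / apod_radius), n, n))
  } else {
    ifftshift2(matrix(as.numeric(centered_radius(n) < apod_radius), n, n))
  }
  list(shifts = shifts, weights = weights, denom = denom, apod = apod,
       Minv = phase_mixing_inverse(raw$phases, raw$modulation_depth),
       apod_radius = apod_radius)
}

#' Merge separated components into one super-resolved image
#'
#' Generalized Wiener combination: each component spectrum, already shifted
#' to its true frequency position, is weighted by its shifted OTF; the
#' weighted sum is divided by the summed squared shifted OTFs plus the
#' squared Wiener constant, apodized, and inverse-transformed (real part).
#'
#' @param components List of complex spectra in native layout, one per
#'   separated component (3 angles x 3 components = 9 entries, center
#'   components included once per angle), each already shifted to its true
#'   position.
#' @param shifts List of the translation vectors that were applied to the
#'   corresponding `components` entries (`c(0, 0)` for center components).
#' @param otf The `otf_model` used in the acquisition.
#' @param config A `reconstruction_config`.
#' @param fringe_period Fringe period in real-domain pixels (sets the
#'   apodization support radius `cutoff + size / fringe_period`).
#' @return Real matrix: the super-resolved image.
#' @export
assemble_hr <- function(components, shifts, otf, config, fringe_period) {
  stopifnot(length(components) == length(shifts))
  n <- otf$size
  num <- matrix(0 + 0i, n, n)
  den <- matrix(config$wiener^2, n, n)
  for (i in seq_along(components)) {
    w <- otf_radial(native_shifted_radius(n, shifts[[i]]) / otf$cutoff)
    num <- num + w * components[[i]]
    den <- den + w^2
  }
  apod_radius <- sim_passband_radius(otf$cutoff, fringe_period, n)
  apod <- if (config$apodization == "triangle") {
    ifftshift2(matrix(pmax(0, 1 - centered_radius(n) / apod_radius), n, n))
  } else {
    ifftshift2(matrix(as.numeric(centered_radius(n) < apod_radius), n, n))
  }
  Re(ifft2(num / den * apod))
}

# One window, using the precomputed plan and cached raw-frame spectra.
reconstruct_window <- function(spectra_cache, start0, raw, plan) {
  n <- raw$size
  num <- matrix(0 + 0i, n, n)
  w_idx <- start0 + 0:8                       # 0-based raw-frame indices
  p_idx <- w_idx %% 9L                        # pattern index per frame
  for (a in 0:2) {
    sel <- which(p_idx %/% 3L == a)           # 3 frames of this angle
    ord <- order(p_idx[sel] %% 3L)            # phase order 0, 2pi/3, 4pi/3
    sel <- sel[ord]
    comps <- separate_from_spectra(spectra_cache[w_idx[sel] + 1L], plan$Minv)
    k <- raw$kvec[a + 1, ]
    num <- num + plan$weights[[1]] * comps$center +
      plan$weights[[2 * a + 2]] * shift_component(comps$plus,  -k) +
      plan$weights[[2 * a + 3]] * shift_component(comps$minus, +k)
  }
  Re(ifft2(num / plan$denom * plan$apod))
}

#' Reconstruct a super-resolved time series
#'
#' Slides a 9-frame window over the raw stack at the scheme's stride and
#' reconstructs each window independently.  Frames within a window are
#' grouped into angle triples by their pattern index (`t mod 9`), so
#' rolling-1 windows whose start is not a multiple of 3 contain one phase
#' triple split between the window's ends; no reordering or interpolation
#' is applied beyond that bookkeeping.  Windows that share a start index
#' across schemes produce bit-identical images.
#'
#' @param raw A `raw_frame_stack` from [acquire_raw_frames()].
#' @param otf The `otf_model` used in the acquisition.
#' @param config A `reconstruction_config`.
#' @return An `hr_stack`: `frames` (size x size x n_windows array),
#'   `window_start` (0-based first raw frame per window), `scheme`,
#'   `size`, `n_windows`, `cutoff`, `fringe_period`, `sim_limit` (rounded
#'   extended pass-band radius).
#' @export
reconstruct_series <- function(raw, otf, config = reconstruction_config()) {
  stopifnot(inherits(raw, "raw_frame_stack"), inherits(otf, "otf_model"),
            inherits(config, "reconstruction_config"))
  if (raw$size != otf$size) stop("grid size mismatch", call. = FALSE)
  if (raw$n_frames < 9) stop("need at least 9 raw frames", call. = FALSE)
  starts <- window_starts(raw$n_frames, config$scheme)
  plan <- make_reconstruction_plan(raw, otf, config)
  spectra_cache <- lapply(seq_len(raw$n_frames),
                          function(t) fft2(raw$frames[, , t]))
  n <- raw$size
  frames <- array(0, dim = c(n, n, length(starts)))
  for (i in seq_along(starts)) {
    frames[, , i] <- reconstruct_window(spectra_cache, starts[i], raw, plan)
  }
  if (config$mean_normalize && length(starts) > 1) {
    ref <- mean(frames[, , 1])
    for (i in seq_along(starts)[-1]) {
      mi <- mean(frames[, , i])
      if (mi != 0) frames[, , i] <- frames[, , i] * (ref / mi)
    }
  }
  structure(
    list(frames = frames, window_start = starts, scheme = config$scheme,
         size = n, n_windows = length(starts), cutoff = raw$cutoff,
         fringe_period = raw$fringe_period,
         sim_limit = sim_passband_limit(raw$cutoff, raw$fringe_period, n)),
    class = "hr_stack"
  )
}

#' @export
print.hr_stack <- function(x, ...) {
  cat(sprintf(
    "<hr_stack> %d windows (%s) of %d x %d px, pass band to %d freq px\n",
    x$n_windows, x$scheme, x$size, x$size, x$sim_limit))
  invisible(x)
}
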