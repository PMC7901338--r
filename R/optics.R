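# Microscope model: incoherent imaging through a circular pupil.  The OTF
# is the autocorrelation of the pupil, which for a circular aperture has
# the closed-form "chord area" profile used below; the corresponding PSF
# (inverse transform of the OTF) is automatically non-negative.

# Normalized autocorrelation of a unit disk at reduced radius rho = r/cutoff.
otf_radial <- function(rho) {
  v <- numeric(length(rho))
  inside <- rho < 1
  p <- rho[inside]
  v[inside] <- (2 / pi) * (acos(p) - p * sqrt(1 - p^2))
  v
}

#' Construct the microscope optical transfer function
#'
#' Builds the 2D OTF of an ideal widefield microscope as the
#' autocorrelation of a circular aperture, evaluated analytically:
#' `(2/pi) * (acos(rho) - rho * sqrt(1 - rho^2))` with `rho = |f| / cutoff`,
#' zero for `rho >= 1` and normalized to 1 at DC.  The transfer matrix is
#' stored in the centered layout (DC at `floor(N/2) + 1`).
#'
#' @param size Grid side length in pixels.
#' @param cutoff Hard cutoff radius in frequency pixels
#'   (`0 < cutoff <= size/2`).  The real-domain cutoff period is
#'   `size / cutoff` pixels.
#' @return An `otf_model` object: list with `transfer` (centered size x size
#'   matrix), `cutoff`, `size`.
#' @examples
#' otf <- make_otf(512, 128)
#' otf$transfer[257, 257]       # 1 at DC
#' 512 / otf$cutoff             # cutoff period: 4 px
#' @export
make_otf <- function(size, cutoff) {
  if (size < 2 || size != round(size)) {
    stop("`size` must be an integer >= 2", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff > size / 2) {
    stop("`cutoff` must satisfy 0 < cutoff <= size/2 (Nyquist)",
         call. = FALSE)
  }
  transfer <- matrix(otf_radial(centered_radius(size) / cutoff), size, size)
  structure(list(transfer = transfer, cutoff = cutoff, size = as.integer(size)),
            class = "otf_model")
}

#' @export
print.otf_model <- function(x, ...) {
  cat(sprintf(
    "<otf_model> %d x %d grid, cutoff %g freq px (period %g px)\n",
    x$size, x$size, x$cutoff, x$size / x$cutoff))
  invisible(x)
}

#' Image a frame through the microscope
#'
#' Low-pass filters an image with the OTF: multiply the 2D Fourier
#' transform by the transfer function and invert.  The boundary condition
#' is periodic (plain transform-multiply, no padding), which is exact for
#' the synthetic periodic samples used here.  The tiny imaginary residue of
#' the inverse transform (float round-off) is discarded.
#'
#' @param image Real square matrix, same side length as the OTF grid.
#' @param otf An `otf_model` from [make_otf()].
#' @return Real matrix of the same size.
#' @export
apply_otf <- function(image, otf) {
  stopifnot(inherits(otf, "otf_model"))
  if (!is_square_matrix(image) || nrow(image) != otf$size) {
    stop("`image` must be a ", otf$size, " x ", otf$size, " matrix",
         call. = FALSE)
  }
  Re(ifft2(fft2(image) * ifftshift2(otf$transfer)))
}

#' Extended pass-band radius of SIM
#'
#' The structured-illumination reconstruction shifts sample spectra by the
#' fringe spatial frequency `size / fringe_period` before merging, so the
#' merged pass band extends to the widefield cutoff plus that shift:
#' `round(cutoff + size / fringe_period)` frequency pixels.  With the
#' default settings (cutoff 128, fringe period 4.75 px on a 512 grid) this
#' is 236 frequency pixels, slightly short of the 256-pixel Nyquist radius
#' because the fringe period must exceed the 4-pixel cutoff period to pass
#' through the objective.
#'
#' @param cutoff Widefield OTF cutoff radius in frequency pixels.
#' @param fringe_period Illumination fringe period in real-domain pixels
#'   (`> 2`, i.e. fringe frequency below Nyquist; `Inf` gives the widefield
#'   limit).
#' @param size Grid side length in pixels.
#' @return Integer pass-band radius in frequency pixels.
#' @examples
#' sim_passband_limit(128, 4.75, 512)  # 236
#' @export
sim_passband_limit <- function(cutoff, fringe_period, size) {
  if (fringe_period <= 2) {
    stop("`fringe_period` must exceed 2 px (fringe frequency below Nyquist)",
         call. = FALSE)
  }
  as.integer(round(cutoff + size / fringe_period))
}

# Exact (non-rounded) pass-band radius, used for apodization support.
sim_passband_radius <- function(cutoff, fringe_period, size) {
  cutoff + size / fringe_period
}
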