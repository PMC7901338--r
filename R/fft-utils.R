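# Fourier-domain helpers shared by the optics, reconstruction and metrics
# code.  Convention: matrices are indexed [y, x] (rows are y); the native
# FFT layout has DC at [1, 1]; the centered layout has DC at
# [floor(N/2) + 1, floor(N/2) + 1].

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Shift the zero-frequency component to the centre of the matrix (and back).
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  i1 <- ((seq_len(n1) - 1 - floor(n1 / 2)) %% n1) + 1
  i2 <- ((seq_len(n2) - 1 - floor(n2 / 2)) %% n2) + 1
  x[i1, i2, drop = FALSE]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  i1 <- ((seq_len(n1) - 1 + floor(n1 / 2)) %% n1) + 1
  i2 <- ((seq_len(n2) - 1 + floor(n2 / 2)) %% n2) + 1
  x[i1, i2, drop = FALSE]
}

# Centered frequency coordinates: integer offsets from DC, -N/2 .. N/2-1
# for even N.
centered_freqs <- function(n) seq_len(n) - 1 - floor(n / 2)

# Matrix of distances from DC in the centered layout.
centered_radius <- function(n) {
  f <- centered_freqs(n)
  fx <- matrix(f, n, n, byrow = TRUE)
  fy <- matrix(f, n, n)
  sqrt(fx^2 + fy^2)
}

# Toroidal (wrap-around) distance from the frequency-space point `centre`
# (x, y components, possibly fractional), evaluated on the native FFT grid.
# Used for the shifted-OTF weights: the spectral shift is implemented as a
# circular translation, so its support wraps the same way.
native_shifted_radius <- function(n, centre) {
  f <- centered_freqs(n)
  wrap <- function(d) ((d + n / 2) %% n) - n / 2
  dx <- wrap(f - centre[1])
  dy <- wrap(f - centre[2])
  r <- sqrt(outer(dy^2, dx^2, "+"))
  ifftshift2(r)
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)
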