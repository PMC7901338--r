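# Shared fixtures, all generated in code.  "tiny" scale (32/64 px) keeps
# unit tests fast; "desk" scale (128 px, cutoff 32, 144 frames) preserves
# the dimensionless ratios of the full-size experiment (cutoff period 4 px,
# fringe period / cutoff period = 1.1875, 16 nine-frame windows).

# Full pipeline at tiny scale; returns the hr_stack.
tiny_pipeline <- function(Tm = 16, n = 64, cutoff = 16, n_frames = 45,
                          scheme = "rolling1", density = 0.01,
                          max_signal = 1, noise = FALSE, seed = 7,
                          apodization = "triangle") {
  s <- generate_point_sample(n, density, max_signal, seed = seed)
  otf <- make_otf(n, cutoff)
  pat <- make_pattern_set(n, 4.75)
  gt <- build_ground_truth_stack(s, n_frames, Tm)
  raw <- acquire_raw_frames(gt, pat, otf, noise_on = noise, seed = seed + 1)
  reconstruct_series(raw, otf,
                     reconstruction_config(scheme, apodization = apodization))
}

# Radial RMSE profile of one desk-scale run; memoized because several
# acceptance checks share runs.
desk_profile <- local({
  cache <- list()
  function(Tm, scheme = "rolling1", noise = FALSE, max_signal = 1,
           seed = 1, registration = "center") {
    key <- paste(Tm, scheme, noise, max_signal, seed, registration,
                 sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- 128; cutoff <- 32
    s <- generate_point_sample(n, 0.01, max_signal, seed = seed)
    otf <- make_otf(n, cutoff)
    pat <- make_pattern_set(n, 4.75)
    gt <- build_ground_truth_stack(s, 144, Tm)
    raw <- acquire_raw_frames(gt, pat, otf, noise_on = noise,
                              seed = seed + 1000)
    hr <- reconstruct_series(raw, otf, reconstruction_config(scheme))
    prof <- radial_average(rmse_map(spectrum_series(hr), Tm, registration))
    cache[[key]] <<- prof
    prof
  }
})

# Desk-scale radial bin index sets (1-based rows of a radial_profile):
# widefield bins 1..cutoff, super-resolved bins cutoff+1..sim limit.
desk_bins <- function() {
  lim <- sim_passband_limit(32, 4.75, 128)   # 59
  list(all = seq_len(lim), widefield = seq_len(32), super = 33:lim)
}

# Numeric OTF oracle: normalized circular autocorrelation of a hard-edged
# pupil disk (radius a; OTF cutoff corresponds to lag 2a), via FFT on a
# fine grid.  Returns the radial profile at integer axis lags 0..2a.
disk_autocorr_oracle <- function(grid = 1024, a = 256) {
  mask <- matrix(as.numeric(centered_radius(grid) <= a), grid, grid)
  A <- Re(stats::fft(Mod(stats::fft(ifftshift2(mask)))^2, inverse = TRUE))
  A[1, seq_len(2 * a + 1)] / A[1, 1]
}

# Access to internal helpers used by oracles.
centered_radius <- simtempres:::centered_radius
ifftshift2 <- simtempres:::ifftshift2
fftshift2 <- simtempres:::fftshift2
fft2 <- simtempres:::fft2
ifft2 <- simtempres:::ifft2
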