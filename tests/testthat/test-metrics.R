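test_that("spectrum magnitudes behave like a centered 2D transform", {
  n <- 32
  # constant frame: only DC is nonzero
  sp <- spectrum_series(array(5, c(n, n, 1)))
  dc <- floor(n / 2) + 1
  m <- sp$magnitudes[, , 1]
  expect_equal(m[dc, dc], 5 * n * n)
  m[dc, dc] <- 0
  expect_lt(max(m), 1e-9)
  # a single unit pixel has a flat spectrum of magnitude 1
  delta <- array(0, c(n, n, 1))
  delta[7, 23, 1] <- 1
  expect_equal(spectrum_series(delta)$magnitudes[, , 1],
               matrix(1, n, n), tolerance = 1e-12)
  # linearity: doubling the frame doubles every magnitude
  set.seed(3)
  fr <- array(rnorm(n * n), c(n, n, 1))
  expect_equal(spectrum_series(2 * fr)$magnitudes,
               2 * spectrum_series(fr)$magnitudes, tolerance = 1e-12)
})

test_that("z-scoring is affine-invariant with population moments", {
  set.seed(4)
  x <- rnorm(50)
  nx <- normalize_trace(x)
  expect_equal(mean(nx$values), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(nx$values^2)), 1, tolerance = 1e-9)
  expect_equal(normalize_trace(3.2 * x + 7)$values, nx$values,
               tolerance = 1e-9)
  expect_error(normalize_trace(rep(2, 10)), class = "simtempres_degenerate_trace")
  expect_error(normalize_trace(1), "length")
})

test_that("RMSE spans [0, 2] and equals sqrt(2(1 - rho))", {
  set.seed(5)
  x <- rnorm(64)
  expect_equal(rmse_trace(x, x), 0)
  expect_equal(rmse_trace(x, -x), 2)
  for (i in 1:25) {
    a <- rnorm(40)
    b <- rnorm(40)
    expect_equal(rmse_trace(a, b), sqrt(2 * (1 - cor(a, b))),
                 tolerance = 1e-9)
  }
  expect_error(rmse_trace(rnorm(10), rnorm(11)), "length")
})

test_that("the power-spectrum dot metric ignores phase and separates divisor tones", {
  t <- 0:63
  g <- sin(2 * pi * t / 16)
  expect_equal(dot_metric(g, g), 1)
  expect_equal(dot_metric(-g, g), 1)                        # anti-phase
  expect_equal(dot_metric(sin(2 * pi * (t + 5) / 16), g), 1,
               tolerance = 1e-9)                            # pure lag
  x <- sin(2 * pi * t / 8)                                  # different divisor tone
  expect_lt(dot_metric(x, g), 1e-9)
  expect_gt(dot_metric(g, g, normalized = FALSE), 0)
  # single-bin power fraction: pure tone concentrates all variance
  expect_equal(temporal_peak_magnitude(g, 4), 1, tolerance = 1e-9)
  expect_lt(temporal_peak_magnitude(x, 4), 1e-9)
})

test_that("rmse_map scores perfect tracking as 0 and anti-phase as 2", {
  n <- 16
  nt <- 24
  set.seed(8)
  g <- modulation_value(0:(nt - 1), 8)
  base <- matrix(runif(n * n) + 0.5, n)
  perfect <- array(as.vector(base), c(n, n, nt)) * rep(g, each = n * n)
  anti <- array(as.vector(base), c(n, n, nt)) * rep(2 - g, each = n * n)
  sp <- spectrum_series(perfect)
  sp$window_start <- 0:(nt - 1)
  m <- rmse_map(sp, 8, registration = "start")
  expect_lt(max(m$values, na.rm = TRUE), 1e-6)
  spa <- spectrum_series(anti)
  spa$window_start <- 0:(nt - 1)
  ma <- rmse_map(spa, 8, registration = "start")
  expect_equal(min(ma$values, na.rm = TRUE), 2, tolerance = 1e-6)
})

test_that("white-noise traces against the modulation average sqrt(2)", {
  nt <- 100
  g <- normalize_trace(modulation_value(0:(nt - 1), 16))$values
  set.seed(6)
  X <- matrix(rnorm(1000 * nt), 1000)
  X <- (X - rowMeans(X)) / sqrt(rowMeans(X^2) - rowMeans(X)^2)
  r <- sqrt(2 * (1 - as.vector(X %*% g) / nt))
  expect_equal(mean(r), sqrt(2), tolerance = 0.05)
  expect_true(all(r >= 0 & r <= 2))
})

test_that("radial averaging bins by floor(radius) and conserves pixel counts", {
  n <- 32
  # map whose value is floor(radius): every bin averages to its own radius
  m <- matrix(floor(centered_radius(n)), n, n)
  prof <- radial_average(m)
  expect_equal(prof$value, prof$radius)
  expect_equal(sum(prof$count), sum(centered_radius(n) < n / 2))
  # brute-force oracle on a random map
  set.seed(7)
  vals <- matrix(rnorm(n * n), n)
  prof2 <- radial_average(vals)
  r <- floor(centered_radius(n))
  for (b in c(0, 1, 5, 11, 15)) {
    expect_equal(prof2$value[b + 1], mean(vals[r == b]))
    expect_equal(prof2$count[b + 1], sum(r == b))
  }
  # constant map averages to the constant everywhere
  expect_true(all(radial_average(matrix(2.5, n, n))$value == 2.5))
  # NA pixels are excluded from means; an all-NA annulus stays missing
  vals[r == 3] <- NA
  vals[which(r == 5)[1]] <- NA
  prof3 <- radial_average(vals)
  expect_true(is.na(prof3$value[4]))
  expect_equal(prof3$count[4], sum(r == 3))   # cardinality kept
  expect_equal(prof3$n_valid[6], sum(r == 5) - 1)
  expect_equal(prof3$value[6], mean(vals[r == 5], na.rm = TRUE))
})

test_that("degenerate pixels are flagged and excluded, not zeroed", {
  n <- 16
  nt <- 12
  # a temporally constant stack makes every Fourier-pixel trace degenerate
  sp <- spectrum_series(array(rep(matrix(runif(n * n), n), nt), c(n, n, nt)))
  sp$window_start <- 0:(nt - 1)
  m <- rmse_map(sp, 5, registration = "start")
  expect_equal(m$n_degenerate, n * n)
  expect_true(all(is.na(m$values)))
  expect_true(all(is.na(radial_average(m)$value)))
})

test_that("scaling the input intensity leaves RMSE maps unchanged", {
  h1 <- tiny_pipeline(Tm = 12, n = 32, cutoff = 8, n_frames = 18,
                      scheme = "rolling3", max_signal = 1)
  h5 <- tiny_pipeline(Tm = 12, n = 32, cutoff = 8, n_frames = 18,
                      scheme = "rolling3", max_signal = 5)
  m1 <- rmse_map(spectrum_series(h1), 12)
  m5 <- rmse_map(spectrum_series(h5), 12)
  both <- !is.na(m1$values) & !is.na(m5$values)
  expect_gt(sum(both), 0.5 * length(both))
  expect_equal(m1$values[both], m5$values[both], tolerance = 1e-9)
  # and the valid-pixel spectra scale exactly with the intensity
  s1 <- spectrum_series(h1)$magnitudes
  s5 <- spectrum_series(h5)$magnitudes
  keep <- rep(both, dim(s1)[3])
  expect_equal(s5[keep], 5 * s1[keep], tolerance = 1e-9)
})

test_that("sweeps assemble radial profiles over periods and subtract cleanly", {
  cfg <- experiment_config(size = 64, cutoff = 16, n_frames = 36,
                           periods = c(4, 12, 18), seed = 3,
                           schemes = "rolling3")
  sw <- sweep_modulation_periods(cfg)
  expect_s3_class(sw, "spatiotemporal_map")
  expect_equal(dim(sw$matrix), c(32, 3))
  expect_equal(sw$periods, c(4, 12, 18))
  # self-difference is zero; (b + c) - b recovers c
  d0 <- difference_map(sw, sw)
  expect_true(all(d0$matrix[!is.na(d0$matrix)] == 0))
  sw2 <- sw
  sw2$matrix <- sw$matrix + 0.25
  expect_equal(difference_map(sw2, sw)$matrix,
               matrix(0.25, 32, 3) + 0 * sw$matrix, tolerance = 1e-12)
  # axis mismatch is refused
  sw3 <- sw
  sw3$periods <- c(4, 12, 20)
  expect_error(difference_map(sw, sw3), "axis")
})

test_that("dot-metric sweeps keep only even integer divisors of the series", {
  cfg <- experiment_config(size = 64, cutoff = 16, n_frames = 36,
                           periods = c(3, 4, 6, 8, 12, 18), seed = 3,
                           schemes = "rolling1")
  sw <- sweep_modulation_periods(cfg, metric = "dot")
  expect_true(all(sw$periods %% 2 == 0))
  expect_true(all(36 %% sw$periods == 0))
  expect_equal(sw$periods, c(4, 6, 12, 18))
  expect_true(all(sw$matrix >= -1e-9 & sw$matrix <= 1 + 1e-9, na.rm = TRUE))
})
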