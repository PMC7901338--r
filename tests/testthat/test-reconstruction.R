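test_that("window schedules have the expected strides and counts", {
  expect_equal(length(window_starts(512, "conventional")), 56)
  expect_equal(length(window_starts(512, "rolling3")), 168)
  expect_equal(length(window_starts(512, "rolling1")), 504)
  # rolling-3 windows start at raw frames 1, 4, 7, ... (1-based)
  expect_equal(window_starts(30, "rolling3") + 1, c(1, 4, 7, 10, 13, 16, 19, 22))
  expect_equal(window_starts(9, "conventional"), 0L)
  expect_error(window_starts(8, "rolling1"), "9")
})

test_that("phase separation inverts the forward mixing exactly", {
  n <- 32
  set.seed(1)
  rnd <- function() matrix(complex(real = rnorm(n * n),
                                   imaginary = rnorm(n * n)), n)
  C0 <- rnd(); Cp <- rnd(); Cm <- rnd()
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  m <- 0.8
  observed <- lapply(phases, function(p) {
    C0 + (m / 2) * exp(1i * p) * Cp + (m / 2) * exp(-1i * p) * Cm
  })
  frames <- lapply(observed, ifft2)  # separate_components transforms back
  out <- separate_components(frames, phases, m)
  expect_lt(max(Mod(out$center - C0)) / max(Mod(C0)), 1e-9)
  expect_lt(max(Mod(out$plus - Cp)) / max(Mod(Cp)), 1e-9)
  expect_lt(max(Mod(out$minus - Cm)) / max(Mod(Cm)), 1e-9)
})

test_that("equal frames at zero modulation depth yield null side components", {
  n <- 16
  f <- matrix(rnorm(n * n), n)
  # m = 0 makes the mixing singular: rejected as ill-conditioned
  expect_error(separate_components(list(f, f, f), c(0, 2 * pi / 3, 4 * pi / 3),
                                   m = 0), "ill-conditioned")
  # equal frames with well-conditioned mixing: side components vanish
  out <- separate_components(list(f, f, f), c(0, 2 * pi / 3, 4 * pi / 3),
                             m = 1)
  expect_lt(max(Mod(out$plus)), 1e-9 * max(Mod(out$center)))
  expect_lt(max(Mod(out$minus)), 1e-9 * max(Mod(out$center)))
  expect_error(separate_components(list(f, f, f), c(0, 0, 0)),
               "ill-conditioned")
})

test_that("spectral shifting obeys the shift theorem", {
  n <- 64
  set.seed(2)
  A <- fft2(matrix(rnorm(n * n), n))
  # zero shift is the identity
  expect_equal(shift_component(A, c(0, 0)), A)
  # integer shift equals an array roll: G(f) = F(f - v)
  v <- c(5, -11)
  B <- shift_component(A, v)
  idx <- function(k, sh) ((k - 1 - sh) %% n) + 1
  expect_equal(B, A[idx(1:n, v[2]), idx(1:n, v[1])], tolerance = 1e-9)
  # fractional shift forward then back is the identity
  w <- c(64 / 4.75, -3.21)
  expect_lt(max(Mod(shift_component(shift_component(A, w), -w) - A)) /
              max(Mod(A)), 1e-9)
  expect_error(shift_component(A, c(40, 0)), "Nyquist")
})

test_that("a uniform sample reconstructs to a uniform image", {
  # a fully grid-commensurate geometry (5-12-13 wave-vectors, all of
  # magnitude 13 on a 64 grid) makes the only-DC-survives identity exact;
  # the default non-integer fringe leaks spectrally under the periodic
  # boundary and is checked loosely
  n <- 64
  otf <- make_otf(n, 16)
  gt <- build_ground_truth_stack(matrix(2, n, n), 9, Tm = 1)
  pyth <- c(0, atan2(5, 12), atan2(12, 5)) * 180 / pi
  pat <- make_pattern_set(n, n / 13, angles = pyth)
  raw <- acquire_raw_frames(gt, pat, otf)
  h <- reconstruct_series(raw, otf,
                          reconstruction_config("conventional"))$frames[, , 1]
  expect_lt(diff(range(h)) / mean(h), 1e-6)
  pat2 <- make_pattern_set(n, 4.75)
  raw2 <- acquire_raw_frames(gt, pat2, otf)
  h2 <- reconstruct_series(raw2, otf,
                           reconstruction_config("conventional"))$frames[, , 1]
  expect_lt(stats::sd(h2) / mean(h2), 0.5)
})

test_that("reconstructed spectra stay inside the extended pass band", {
  hr <- tiny_pipeline(Tm = 16, n_frames = 9, scheme = "conventional")
  H <- Mod(fftshift2(fft2(hr$frames[, , 1])))
  r <- centered_radius(64)
  expect_lt(max(H[r > hr$sim_limit + 2]), 1e-6 * max(H))
})

test_that("two points 3 px apart are resolved by SIM but not widefield", {
  n <- 128
  ph <- matrix(0, n, n)
  ph[65, 64] <- 1
  ph[65, 67] <- 1
  otf <- make_otf(n, 32)              # cutoff period 4 px
  pat <- make_pattern_set(n, 4.75)
  gt <- build_ground_truth_stack(ph, 9, Tm = 1)
  raw <- acquire_raw_frames(gt, pat, otf)
  h <- reconstruct_series(raw, otf,
                          reconstruction_config("conventional"))$frames[, , 1]
  wf <- apply_otf(ph, otf)
  dip <- function(p) 1 - min(p[65:66]) / min(p[64], p[67])
  expect_gte(dip(h[65, ]), 0.10)       # resolved, >= 10% intensity dip
  expect_lte(dip(wf[65, ]), 0)         # widefield: maximum between points
})

test_that("rolling-1 windows at conventional starts are bit-identical to conventional", {
  n <- 64
  s <- generate_point_sample(n, 0.01, 1, seed = 9)
  otf <- make_otf(n, 16)
  pat <- make_pattern_set(n, 4.75)
  gt <- build_ground_truth_stack(s, 27, 16)
  raw <- acquire_raw_frames(gt, pat, otf)
  conv <- reconstruct_series(raw, otf, reconstruction_config("conventional"))
  r1 <- reconstruct_series(raw, otf, reconstruction_config("rolling1"))
  expect_equal(conv$window_start, c(0L, 9L, 18L))
  at <- match(conv$window_start, r1$window_start)
  expect_identical(conv$frames, r1$frames[, , at])
})

test_that("constant modulation yields identical frames across a rolling series", {
  hr <- tiny_pipeline(Tm = 1, n_frames = 20, scheme = "rolling1")
  ref <- hr$frames[, , 1]
  for (i in 2:hr$n_windows) {
    expect_lt(max(abs(hr$frames[, , i] - ref)), 1e-9 * max(abs(ref)))
  }
})

test_that("rolling window grouping keeps complete phase triples per angle", {
  # rolling-3 starts are multiples of 3: each angle's three pattern indices
  # appear consecutively; rolling-1 offsets not divisible by 3 split one
  # triple between the window ends
  for (s in window_starts(21, "rolling3")) {
    p <- (s + 0:8) %% 9
    for (a in 0:2) {
      pos <- which(p %/% 3 == a)
      expect_equal(diff(range(pos)), 2)   # contiguous triple
    }
  }
  split_count <- vapply(window_starts(21, "rolling1"), function(s) {
    p <- (s + 0:8) %% 9
    sum(vapply(0:2, function(a) diff(range(which(p %/% 3 == a))) > 2,
               logical(1)))
  }, numeric(1))
  expect_true(all(split_count[window_starts(21, "rolling1") %% 3 == 0] == 0))
  expect_true(all(split_count[window_starts(21, "rolling1") %% 3 != 0] == 1))
})

test_that("reconstruction configuration validates its inputs", {
  expect_error(reconstruction_config(wiener = 0), "wiener")
  expect_error(reconstruction_config("sliding"))
  cfg <- reconstruction_config("rolling3", apodization = "none")
  expect_equal(cfg$stride, 3L)
})
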