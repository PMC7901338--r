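# simtempres

Measuring the temporal resolution of structured illumination microscopy
(SIM), spatial frequency by spatial frequency.

SIM buys its two-fold spatial-resolution gain with time: nine raw frames
(3 illumination angles × 3 phases) per super-resolved image.  "Rolling"
reconstruction schedules re-use raw frames in overlapping windows and are
widely assumed to recover temporal resolution.  `simtempres` puts that
assumption under a quantitative microscope.  It simulates a complete SIM
time-lapse experiment — sparse point emitters, a known sinusoidal
intensity modulation, ideal circular-pupil optics, nine-pattern fringe
acquisition, optional Poisson noise, Wiener-filter reconstruction under
conventional (stride 9), rolling-3 and rolling-1 schedules — and scores
every spatial frequency's temporal fidelity against the known modulation.

## The method in brief

The sample intensity is modulated by `G(t) = 0.75 + sin(2πt/Tm)/4`.  By
linearity of the Fourier transform, every magnitude `|I(fx, fy, t)|` of a
faithful reconstruction `H(x, y, t)` must follow `G(t)`.  For each Fourier
pixel the package z-scores the magnitude trace `Ĩ = (I − Ī)/σ_I` and
computes

```
RMSE(fx, fy) = sqrt( Σ_t (Ĩ(fx, fy, t) − G̃(t))² / n_t )
```

which is 0 for perfect tracking, 2 in exact anti-phase, and √2 for
uncorrelated traces (algebraically `RMSE = sqrt(2(1 − ρ))`, ρ the Pearson
correlation).  Maps are radially averaged over annuli `[r, r+1)` and
stacked over modulation periods into spatial-frequency × period heatmaps;
a phase-insensitive alternative compares temporal *power spectra*
(`dot_metric()`).  The microscope model is the autocorrelation-of-a-pupil
OTF with a hard cutoff (cutoff period 4 px); the 4.75 px illumination
fringe extends the reconstructed pass band to `cutoff + N/4.75` frequency
pixels — 236 of 256 (Nyquist) on the full 512 px grid.

## Worked example

```r
library(simtempres)

sample   <- generate_point_sample(size = 64, density = 0.01, seed = 1)
otf      <- make_otf(64, cutoff = 16)
patterns <- make_pattern_set(64, fringe_period = 4.75)

gt  <- build_ground_truth_stack(sample, n_frames = 45, Tm = 16)
raw <- acquire_raw_frames(gt, patterns, otf)
hr  <- reconstruct_series(raw, otf, reconstruction_config("rolling1"))
hr
#> <hr_stack> 37 windows (rolling1) of 64 x 64 px, pass band to 29 freq px

prof <- radial_average(rmse_map(spectrum_series(hr), Tm = 16))
round(subset(prof, radius %in% c(0, 4, 8, 12, 16, 20, 24, 28)), 3)
#>    radius value count n_valid
#> 1       0 0.039     1       1
#> 5       4 0.301    24      24
#> 9       8 0.613    56      56
#> 13     12 0.899    80      80
#> 17     16 0.940    96      96
#> 21     20 0.923   124     124
#> 25     24 0.968   152     152
#> 29     28 0.964   168      86

mean(prof$value[2:16])    # widefield bins (radius 1..15)
#> [1] 0.574
mean(prof$value[17:29])   # super-resolved bins (radius 16..28)
#> [1] 0.947
```

Reading: at a modulation period of 16 frames (≈ 1.8× the nine-frame
window), low spatial frequencies track the modulation closely (RMSE 0.04
at DC, 0.3 at radius 4) while frequencies beyond the widefield cutoff
(radius 16 on this grid) sit near RMSE ≈ 0.95 — the temporal resolution
of the super-resolved content is markedly worse than that of the
widefield content of the very same images.  `sweep_modulation_periods()`
/ `run_experiment()` repeat this over many periods and schemes and write
CSV maps, PNG heatmaps and a manifest; `run_figure_suite("desk")`
produces the four standard summary figures in a few minutes on one CPU.

A command-line wrapper with `simulate`, `reconstruct`, `assess` and
`suite` subcommands is installed at `exec/simtempres` inside the package
library (raw stacks travel as multi-page 32-bit float TIFF with a YAML
sidecar).

## Package layout

- `R/sample.R` — point-emitter sample, modulation trace, ground-truth stack
- `R/optics.R` — analytic OTF, low-pass imaging, extended pass-band limit
- `R/acquisition.R` — nine-pattern fringe set, raw-frame formation, Poisson noise
- `R/reconstruction.R` — phase separation, sub-pixel spectral shift, Wiener merge, window schedules
- `R/metrics.R` — spectrum tracking, z-scored RMSE, radial averaging, dot metric, sweeps
- `R/config.R`, `R/experiment.R`, `R/cli.R` — configuration, experiment driver, figure suite, CLI
- `vignettes/sim-temporal-resolution.Rmd` — the model, its assumptions and design choices
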