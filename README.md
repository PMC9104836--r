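# admmFPM

Blind phase retrieval for Fourier ptychographic microscopy (FPM) by the
alternating direction method of multipliers, with the simulation and
evaluation machinery needed to study it: an LED-array forward-model
simulator with Gaussian/Poisson darkfield noise, two sequential baseline
solvers (Gauss–Newton with self-adaptive step size, and
momentum-accelerated PIE), SSIM evaluation with ambiguity-aware
alignment, dataset/reconstruction I/O, and experiment drivers.

FPM synthesizes a high-NA aperture from many low-resolution intensity
images captured under angularly varied LED illumination: each capture
sees one circular window of the object spectrum through the objective
pupil,

```
I_j = | F^H { p ⊙ Q_j F u } |²
```

with object `u`, unitary Fourier transform `F`, spectrum window `Q_j`,
and pupil `p` (a circular aperture whose interior phase encodes the
objective's aberrations). Both `u` and `p` are unknown. The ADMM solver
splits the problem with per-illumination variables `q_j = p ⊙ Q_j s`
(`s = F u`) and alternates four closed-form updates — a relaxed
projection onto the measured amplitudes, a diagonal Tikhonov-regularized
solve for `s` anchored to the flat-field spectrum, a per-pixel ridge
solve for the pupil, and a multiplier ascent — monitoring normalized
primal/dual error metrics for stopping. The practical payoff of this
global, highly parallel formulation is noise robustness: as darkfield
noise grows, its reconstruction quality declines more slowly than the
sequential solvers'.

Audience: computational-imaging researchers and microscopy method
developers who want a self-contained, tested reference implementation to
benchmark reconstruction algorithms under controlled noise.

## Worked example

```r
library(admmFPM)

cfg    <- opticalConfigSmall()                     # 9x9 LEDs, 64 -> 192 px
truth  <- syntheticGroundTruth(cfg, seed = 1)
pupil  <- makePupil(cfg, zernike = c(0, 0, 0, 0.5, 0.3))  # defocus + astigmatism
ms     <- simulateDataset(cfg, truth, pupil)
noisy  <- addGaussianNoise(ms, level = 0.7, seed = 2)      # 70% darkfield noise

rec <- fpmADMM(noisy)                              # alpha 0.5, beta 1000, gamma 0.3
rec
#> FPMReconstruction [admm]: 192 x 192 object, 84 iteration(s), stop: tolerance
#>   final Ep = 0.002563, Ed = 2.524

evaluateReconstruction(rec, truth)
#> $amplitudeSSIM
#> [1] 0.866989
#> $phaseSSIM
#> [1] 0.8701535
```

`Ep` is the normalized amplitude misfit of the measurements (0.25% here:
the solver explains essentially all signal and stops once both error
metrics stabilize); the SSIMs compare the aligned reconstruction with
the known ground truth, amplitude and phase separately. Run
`runNoiseComparison()` to tabulate the three solvers over noise grids
and seeds, or use the CLI (`inst/cli/fpm.R`) for
`simulate` / `reconstruct` / `evaluate` / `compare` from a shell.

## Package layout

| Area | Files |
|---|---|
| Forward model & simulator | `R/optics.R`, `R/zernike.R`, `R/truth.R`, `R/noise.R` |
| ADMM solver | `R/admm.R` |
| Baselines | `R/baselines.R` |
| Metrics & alignment | `R/metrics.R` |
| I/O containers | `R/io.R` |
| Experiment drivers / CLI | `R/experiments.R`, `inst/cli/fpm.R` |

The methods vignette (`vignettes/fpm-admm-methods.Rmd`) documents the
model, the update derivations, parameter conventions (including the
pupil-ridge scale bridge), noise-model semantics, and known limitations.
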