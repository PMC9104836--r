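---
title: "Blind FPM phase retrieval by ADMM: model, solvers, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blind FPM phase retrieval by ADMM: model, solvers, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admmFPM)
```

## The imaging model

Fourier ptychographic microscopy (FPM) records a stack of low-resolution
intensity images of a thin sample under angularly varied LED illumination.
A tilted plane wave shifts the object spectrum, so each capture sees a
different circular sub-aperture of the object's Fourier transform through
the objective pupil:

$$ I_j \;=\; \bigl|\,\mathcal{F}^{H}\{\, p \odot Q_j\, \mathcal{F} u \,\}\bigr|^2 , $$

where $u$ is the complex object on the high-resolution (HR) grid,
$\mathcal{F}$ the unitary 2-D Fourier transform, $Q_j$ the
low-resolution (LR) window of the HR spectrum selected by the $j$-th
illumination angle, and $p$ the pupil — a circular aperture whose interior
phase carries the objective's aberrations. Both the object and the pupil
are unknown: reconstruction is *blind* phase retrieval, and the package
recovers both.

All transforms in this package are unitary, so Parseval's identity holds
exactly and the adjoint of $Q_j$ (zero-padded embedding) is its exact
transpose. The measured stacks are intensities; the solvers consume
amplitudes $A_j = \sqrt{I_j}$, because the magnitude-projection update
below is dimensionally consistent only for amplitudes. Stacks are
normalized so the brightest brightfield frame has mean 1, which gives the
darkfield threshold of the noise models (0.2) its meaning, and the solvers
rescale amplitudes by `hrSide/lrSide` so that a flat unit-transmittance
object produces unit-scale model fields under the unitary convention.

## The ADMM solver

With the splitting $q_j = p \odot Q_j s$ ($s = \mathcal{F}u$), the
regularized problem

$$ \min_{s,p,\{q_j\}} \sum_j \bigl\| |\mathcal{F}^H q_j| - A_j \bigr\|^2
   \;+\; \tfrac{\gamma}{2}\, \| s - \delta \|^2 $$

is handled by scaled-form ADMM with penalty $\alpha$ and multipliers
$\omega_j$. Here $\delta$ is the spectrum of a flat, phase-free field: a
Tikhonov anchor appropriate for thin, weak-phase specimens, which damps
crosstalk between object and pupil. One iteration performs, in batch:

1. **Magnitude relaxation** for every $j$: with
   $\tilde q = p \odot Q_j s - \omega_j$ and spatial field
   $e = \mathcal{F}^H \tilde q$,
   $\; q_j \leftarrow \tilde q + \frac{1}{1+\alpha}\bigl(\mathcal{F}[A_j
   \odot e/|e|] - \tilde q\bigr)$. At $\alpha = 0$ this is the exact
   projection onto the measured-amplitude set; as $\alpha \to \infty$ the
   update freezes. Pixels with $|e| = 0$ keep phase 0 by convention.
2. **Object solve**: the regularized least-squares problem in $s$ is
   diagonal, $\; s \leftarrow \bigl[\gamma\delta/\alpha + \sum_j Q_j^T(
   \bar p \odot (q_j+\omega_j))\bigr] \big/ \bigl[\gamma/\alpha + \sum_j
   Q_j^T |p|^2\bigr]$. HR bins never covered by any window are anchored to
   $\delta$ when $\gamma > 0$ and frozen when $\gamma = 0$.
3. **Pupil solve**: per-pixel ridge regression,
   $\; p \leftarrow \sum_j \overline{Q_j s} \odot (q_j+\omega_j) \big/
   \bigl(\sum_j |Q_j s|^2 + \beta_\mathrm{eff}\bigr)$, re-masked to the
   aperture support. Both numerator and denominator use the just-updated
   $s$ (the consistent least-squares solution).
4. **Multiplier ascent**: $\omega_j \leftarrow \omega_j + \eta\,(q_j - p
   \odot Q_j s)$.

Each update is the exact minimizer of its subproblem; the test suite
verifies this against independent numeric minimizers (derivative-free
per-pixel optimization for $q$, a dense normal-equations solve for $s$,
stacked-QR least squares for $p$).

### Parameters

| Parameter | Default | Role |
|---|---|---|
| `alpha` | 0.5 | splitting penalty; relaxation weight of the magnitude projection |
| `beta` | 1000 | pupil ridge, quoted on the unnormalized-DFT power scale (below) |
| `gamma` | 0.3 | Tikhonov weight toward the flat-field spectrum |
| `eta` | 1 | multiplier step |
| `epsTol` | 1e-3 | stopping tolerance on both error metrics |
| `maxIter` | 100 | iteration cap |

**The `beta` scale.** The conventional value $\beta = 1000$ is meaningful
only relative to the power carried by the spectra in the pupil-update
denominator. Community implementations build those spectra with
unnormalized DFTs, whose entries carry `lrSide^2` times the power of the
unitary spectra used here; `betaScale = "dft"` (the default) therefore
divides `beta` by `lrSide^2` to apply the equivalent ridge, and
`betaScale = "raw"` applies it verbatim. With the raw interpretation at
unitary scale, a ridge of 1000 overwhelms the data term across most of the
aperture and the pupil estimate collapses toward zero at weakly driven
pixels. The other parameters are ratios of commensurate quantities and
need no bridge.

**Initialization.** The default start is the flat all-ones field
(`initMode = "ones"`), which works best for this solver; the
Fourier-embedded upsampled centre-LED image (`"upsampled"`) is the
conventional warm start of the sequential solvers and is also available.
Multipliers start at zero and $q_j^0 = p^0 \odot Q_j s^0$, so the
splitting residual is exactly zero at $k = 0$.

**Stopping.** The solver monitors the normalized primal metric
$E_p = \sum_j \||\mathcal{F}^H q_j| - A_j\|^2 / \sum_j \|A_j\|^2$ (the
measurement-space form; the splitting-space primal residual is a
different quantity, and the measurement-space form is the operative
choice here) and the normalized dual metric
$E_d = (\alpha/\eta) \sum_j \|q_j^k - q_j^{k-1}\|^2 / \sum_j
\|\lambda_j\|^2$ with $\lambda_j = \alpha\,\omega_j$. Iteration stops when
the relative changes of **both** metrics fall within `epsTol`. Two
numerical choices matter: the relative change uses the absolute value
(a signed criterion would be satisfied by any decrease, stopping at the
first improving step, which cannot be the intent of "converged to a
stable level"), and an unavailable dual metric (multipliers still zero,
or fewer than two values) counts as an infinite change, so it passes only
an infinite tolerance — which makes `epsTol = Inf` terminate after
exactly one iteration, a useful degenerate contract. $E_p$ is invariant
under joint rescaling of data and iterates, and $E_d$ is reported as `NA`
rather than dividing by a zero multiplier norm.

**Schedules.** The batch schedule (all $q_j$, then $s$, $p$, $\omega_j$)
is the parallel form implied by the update derivation and is the default;
a `"sequential"` schedule that nests the $s$ and $p$ solves inside the
per-illumination loop is available for comparison but costs a full
accumulation pass per illumination. Illuminations are swept in
NA-ascending order (centre of Fourier space outward), ties broken by LED
(row, column).

## Baseline solvers

Two sequential solvers share the forward model, containers and error
metric, giving a fair three-way comparison:

* **Sequential Gauss–Newton** with self-adaptive steps: per illumination,
  pupil-weighted quotient updates of the object window and spectrum-
  weighted updates of the pupil (normalized by the maximum modulus of the
  weighting function, with a small relative floor in the denominators);
  after each sweep both step sizes follow the halving rule — halve when
  the error metric rose by more than `epsStep = 0.01` in signed relative
  terms, keep otherwise. Its warm start is the Fourier-upsampled
  centre-LED amplitude.
* **mPIE**: rPIE-style regularized quotient updates
  (object denominator $(1-\alpha)|p|^2 + \alpha|p|^2_{\max}$ with
  $\alpha = 0.1$), pupil updates delayed until the `tPupil = 15`-th
  illumination update, and heavy-ball momentum: after each sweep the
  velocity $v \leftarrow \eta\, v + \Delta$ adds a further step
  $\gamma\,\eta\, v$ ("a bold extra step along the recent trajectory").
  The momentum weights are $\eta_\mathrm{obj} = 0.9$,
  $\eta_\mathrm{pupil} = 0.3$, friction $\gamma = 1$. The source method
  is defined for real-space ptychographic probes; its probe-update
  normalization by the global spectrum maximum transfers poorly to the
  Fourier-domain pupil, whose partner spectrum spans many orders of
  magnitude — with it, pupil recovery stalls far from the true
  aberration. The pupil step here therefore uses the per-pixel
  normalized quotient standard for pupil recovery in FPM, weighted by the
  solver's $\beta = 0.8$. Momentum is what makes the method fast on
  clean data and erratic under heavy noise; both behaviours are visible
  in the comparison driver's error histories.

## Noise models

Only frames whose mean intensity falls below 0.2 (darkfield captures,
which carry the weak high-frequency signal) receive noise:

* **Gaussian** (readout): zero-mean with standard deviation
  `level * mean(frame)`; "70% noise" is `level = 0.7`. Negative
  intensities are clipped to zero, as detectors are nonnegative.
* **Poisson** (shot): each pixel is replaced by
  `sigma * Poisson(I/sigma)`. The mean is preserved exactly and the
  variance is `sigma * I`, so relative fluctuation grows with `sigma`
  (at `sigma -> 0` the model concentrates on the noiseless value). This
  mean-preserving scaling is one of several readings of "Poisson noise
  whose mean is the intensity over sigma"; it is the only one that keeps
  the stack's brightness scale intact, which the threshold rule relies
  on.

Draws are seeded and bit-reproducible, and the injected conditions are
recorded in the dataset's `noiseRecord`.

## Evaluation

Phase retrieval determines the object only up to a global phase, a global
intensity scale, and (in general) a translation. `alignForEval()` removes
these — complex inner-product alignment for the global factor, FFT
cross-correlation for integer shifts — before `fpmSSIM()` scores
amplitude and phase. SSIM follows the standard windowed formulation
(11-pixel Gaussian window, $\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$ on
the joint dynamic range); a single-window global variant is available via
`method = "global"`, as the windowing choice is a convention. Phase maps
are shifted by one common constant into the nonnegative range before
scoring, since the index is defined for nonnegative images. Pupil
recovery is scored as the Pearson correlation of aberration phase inside
the aperture after piston removal.

## The synthetic ground truth

`syntheticGroundTruth()` builds seeded amplitude and phase images as
mixtures of two band-limited Gaussian random fields (cutoffs 0.12 and
0.35 of the grid Nyquist frequency), amplitude in [0.3, 1] and phase in
[0, pi/2] — the weak-phase regime of thin sections in which the flat-field
anchor is a sensible prior. The fields emulate the multi-scale smooth
texture of stained tissue, not any particular specimen; they contain
negligible energy beyond the synthetic aperture of the default platform,
so reconstruction error measures solver behaviour rather than
out-of-band content. Real data additionally contain LED misalignment,
vignetting, intensity miscalibration and spatially structured noise that
the simulator deliberately omits — passing tests here demonstrate
correctness of the solvers under the stated model, not robustness to
those instrument effects.

The default platform mirrors a standard desktop FPM setup: 6.5 µm sensor
pixels behind a 4×/0.1 NA objective, a 15 × 15 LED array 86 mm above the
sample at 4 mm pitch, 632 nm illumination, 128 × 128 measurement patches
reconstructed at 384 × 384. A reduced profile (9 × 9 LEDs, 64 → 192) runs
the same geometry at desk scale; the test suite uses still smaller
configurations (3 × 3/16 → 32 and 5 × 5/32 → 96) for unit and property
tests, the full platform for the end-to-end recovery checks, and the
reduced profile for multi-seed noise sweeps.

## Numerical choices and degenerate inputs

* Even grid sides are required, so the quadrant swap is an involution and
  the DC bin sits at `n/2 + 1`.
* LED tilt frequencies are rounded to the nearest integer HR bin in one
  place (`ledIlluminations()`); windows that would leave the grid raise
  an error rather than wrap.
* `|e| = 0` pixels take phase 0 in magnitude projections.
* Zero-denominator HR bins in the object solve (possible only with
  `gamma = 0`) keep their previous value.
* The divergence guard aborts a solver whose error metric exceeds
  $10^6$ times its initial value.
* The dataset container stores stacks as 32-bit float TIFF scaled into
  [0, 1] with the scale recorded in the metadata (the TIFF writer clamps
  out-of-range values); round trips are exact at the container's declared
  storage precision.

## Known limitations

* On clean data the ADMM solution is the $\gamma$-regularized compromise:
  the flat-field anchor selects, among near-data-consistent objects, one
  with suppressed low-frequency phase structure (the component that
  intensity measurements under a small aperture constrain most weakly).
  Its noiseless SSIM therefore sits below the sequential solvers — the
  data misfit keeps falling while the image similarity saturates — and
  the effect strengthens with $\gamma$ within its suggested 0.1–0.5
  range. The regularization is aimed at noise robustness: in the sweeps
  reproduced by `scripts/acceptance.R`, ADMM shows the smallest
  clean-to-noisy SSIM drop of the three solvers, though from a lower
  clean baseline.
* Relative-change stopping criteria measure decay rate, not proximity to
  a limit: on noiseless double-precision data the error metrics decay
  geometrically without plateauing, so such criteria never fire and runs
  end at the iteration cap. Under noise, genuine plateaus exist and the
  criteria terminate runs early. Convergence *speed* comparisons in the
  tests therefore use iterations to a common absolute error level.
* The mPIE momentum form is a reconstruction from the method's published
  description with its stated parameters; the original formulation prints
  no FPM-specific equations, so the pupil-step normalization is this
  package's adaptation (see the baselines section).
* No LED-position calibration, vignetting correction, or full-FOV patch
  stitching: the package addresses single-patch reconstruction.
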