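# Procedural ground-truth generator: seeded, band-limited random fields so
# that amplitude and phase carry distinct smooth structure plus finer
# texture. Thin biological sections are weak-phase objects, so the phase is
# scaled to [0, pi/2].

bandLimitedField <- function(n, cutoff) {
  # white noise low-passed with a Gaussian radial filter; `cutoff` is the
  # e^-1 frequency as a fraction of the grid Nyquist frequency
  w <- matrix(stats::rnorm(n * n), n, n)
  u <- ((1:n) - (n / 2 + 1)) / (n / 2)   # normalized frequency, Nyquist = 1
  fr <- sqrt(outer(u^2, u^2, "+"))
  filt <- exp(-(fr / cutoff)^2)
  f <- Re(iftc(ftc(w) * filt))
  (f - min(f)) / (max(f) - min(f))
}

#' Generate a synthetic ground-truth object
#'
#' Produces a seeded, procedural complex object on the high-resolution
#' grid: amplitude and phase are independent mixtures of a coarse and a
#' fine band-limited random field, giving smooth structure with texture at
#' several scales (the character of a stained thin tissue section, without
#' claiming to reproduce any particular specimen). The amplitude spans
#' `ampRange` and the phase `[0, phaseMax]` radians; the default
#' `phaseMax = pi/2` respects the weak-phase regime in which the Tikhonov
#' flat-field anchor of the ADMM solver is meaningful.
#'
#' Both fields are essentially band-limited to well below the grid Nyquist
#' frequency, as natural microscopy images are; frequencies beyond the
#' synthetic aperture of the default platform carry negligible energy.
#'
#' @param config an [OpticalConfig-class] (only `hrSide` is used).
#' @param seed integer seed; the generator is fully reproducible.
#' @param ampRange length-2 numeric, amplitude range (min > 0 avoids
#'   zero-transmittance pixels).
#' @param phaseMax maximum phase in radians.
#' @param cutoffs length-2 numeric, Gaussian frequency cutoffs of the
#'   coarse and fine field as fractions of Nyquist.
#' @return an [FPMGroundTruth-class].
#' @examples
#' gt <- syntheticGroundTruth(opticalConfigSmall(), seed = 7)
#' range(gt@amplitude); range(gt@phase)
#' @export
syntheticGroundTruth <- function(config, seed = 1,
                                 ampRange = c(0.3, 1),
                                 phaseMax = pi / 2,
                                 cutoffs = c(0.12, 0.35)) {
  n <- config@hrSide
  withSeed(seed, {
    amp <- 0.75 * bandLimitedField(n, cutoffs[1]) +
           0.25 * bandLimitedField(n, cutoffs[2])
    pha <- 0.75 * bandLimitedField(n, cutoffs[1]) +
           0.25 * bandLimitedField(n, cutoffs[2])
    amp <- (amp - min(amp)) / (max(amp) - min(amp))
    pha <- (pha - min(pha)) / (max(pha) - min(pha))
    new("FPMGroundTruth",
        amplitude = ampRange[1] + diff(ampRange) * amp,
        phase = wrapPhase(phaseMax * pha))
  })
}
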