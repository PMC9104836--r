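#' Inject noise into darkfield measurements
#'
#' Both models emulate detector noise on the weak, high-angle frames: only
#' images whose mean intensity falls below `threshold` are touched (the
#' simulator normalizes stacks so the brightest brightfield image has mean
#' 1, which gives the default threshold of 0.2 its meaning).
#'
#' `addGaussianNoise()` adds zero-mean Gaussian noise with standard
#' deviation `level * mean(image)` to each affected image (readout noise;
#' "70% noise" is `level = 0.7`), clipping negative intensities to zero.
#'
#' `addPoissonNoise()` replaces each affected pixel by
#' `sigma * Poisson(I / sigma)` (photon shot noise): the mean is preserved
#' and the relative fluctuation grows as `sigma` increases, so `sigma` and
#' noise level are inversely related in the usual photon-count sense of
#' the parameterization, where `I / sigma` plays the role of the expected
#' count.
#'
#' @param ms an [FPMMeasurements-class].
#' @param level Gaussian noise level as a fraction of the per-image mean;
#'   must be >= 0 (0 is the identity).
#' @param sigma Poisson scale parameter; must be > 0. Small values
#'   approach the noiseless limit.
#' @param threshold mean-intensity threshold below which a frame is
#'   considered darkfield and receives noise.
#' @param seed integer seed; draws are bit-reproducible.
#' @return a new [FPMMeasurements-class] with updated intensities and
#'   `noiseRecord`.
#' @examples
#' cfg <- opticalConfigSmall(lrSide = 16, hrSide = 48, ledRows = 3, ledCols = 3)
#' ms <- simulateDataset(cfg, syntheticGroundTruth(cfg, seed = 1))
#' noisy <- addGaussianNoise(ms, level = 0.7, seed = 2)
#' noiseRecord(noisy)$model
#' @export
addGaussianNoise <- function(ms, level, threshold = 0.2, seed = NULL) {
  stopifnot(is(ms, "FPMMeasurements"))
  if (level < 0) stop("noise level must be nonnegative")
  I <- ms@intensities
  means <- apply(I, 3, mean)
  affected <- which(means < threshold)
  if (level > 0 && length(affected)) {
    withSeed(seed, {
      for (j in affected) {
        img <- I[, , j]
        img <- img + stats::rnorm(length(img), 0, level * mean(img))
        I[, , j] <- pmax(img, 0)
      }
    })
  }
  new("FPMMeasurements", intensities = I, illuminations = ms@illuminations,
      config = ms@config,
      noiseRecord = list(model = "gaussian", level = level, seed = seed,
                         threshold = threshold,
                         affected = if (level > 0) affected else integer()))
}

#' @rdname addGaussianNoise
#' @export
addPoissonNoise <- function(ms, sigma, threshold = 0.2, seed = NULL) {
  stopifnot(is(ms, "FPMMeasurements"))
  if (sigma <= 0) stop("sigma must be positive")
  I <- ms@intensities
  means <- apply(I, 3, mean)
  affected <- which(means < threshold)
  if (length(affected)) {
    withSeed(seed, {
      for (j in affected) {
        img <- I[, , j]
        I[, , j] <- sigma * stats::rpois(length(img), img / sigma)
      }
    })
  }
  new("FPMMeasurements", intensities = I, illuminations = ms@illuminations,
      config = ms@config,
      noiseRecord = list(model = "poisson", level = sigma, seed = seed,
                         threshold = threshold, affected = affected))
}
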