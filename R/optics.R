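#' Construct an optical configuration
#'
#' The defaults reproduce the simulated acquisition platform used throughout
#' the package's examples: a 6.5 um sensor behind a 4x / 0.1 NA objective,
#' a 15 x 15 LED array 86 mm above the sample with 4 mm pitch, 632 nm
#' illumination, 128 x 128 measurement patches reconstructed on a 384 x 384
#' grid. `opticalConfigSmall()` is a reduced desk-scale profile (9 x 9 LEDs,
#' 64 -> 192 pixels) for quick experiments and tests.
#'
#' A warning (not an error) is issued when the high-resolution grid cannot
#' represent the full synthetic aperture at Nyquist; reconstructions then
#' lose the outermost recorded frequencies.
#'
#' @param wavelength illumination wavelength, micrometres.
#' @param magnification objective magnification.
#' @param objectiveNA objective numerical aperture.
#' @param sensorPixel sensor pixel pitch, micrometres.
#' @param ledRows,ledCols LED-array dimensions.
#' @param ledPitch LED spacing, millimetres.
#' @param ledHeight LED height above the sample, millimetres.
#' @param lrSide,hrSide even pixel counts of the measurement and
#'   reconstruction grids.
#' @return an [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' fourierPitch(cfg)     # frequency-bin spacing, cycles/um
#' pupilRadiusPx(cfg)    # ~32.9 px aperture radius
#' @export
opticalConfig <- function(wavelength = 0.632, magnification = 4,
                          objectiveNA = 0.1, sensorPixel = 6.5,
                          ledRows = 15, ledCols = 15,
                          ledPitch = 4, ledHeight = 86,
                          lrSide = 128, hrSide = 384) {
  cfg <- new("OpticalConfig",
    wavelength = wavelength, magnification = magnification,
    objectiveNA = objectiveNA, sensorPixel = sensorPixel,
    ledRows = ledRows, ledCols = ledCols,
    ledPitch = ledPitch, ledHeight = ledHeight,
    lrSide = lrSide, hrSide = hrSide)
  # Nyquist check for the synthetic aperture on the HR grid
  naSyn <- objectiveNA + maxIllumNA(cfg)
  fMax <- 1 / (2 * objectPixel(cfg) * lrSide / hrSide)
  if (naSyn / wavelength > fMax)
    warning(sprintf(paste0(
      "HR grid undersamples the synthetic aperture: max frequency %.3g/um",
      " < synthetic-NA frequency %.3g/um"), fMax, naSyn / wavelength))
  cfg
}

#' @rdname opticalConfig
#' @export
opticalConfigSmall <- function(ledRows = 9, ledCols = 9,
                               lrSide = 64, hrSide = 192, ...) {
  opticalConfig(ledRows = ledRows, ledCols = ledCols,
                lrSide = lrSide, hrSide = hrSide, ...)
}

#' Derived grid quantities
#'
#' `objectPixel()` is the object-plane pixel size (sensor pixel divided by
#' magnification, micrometres). `fourierPitch()` is the frequency-bin
#' spacing `1 / (lrSide * objectPixel)` in cycles/um, shared by the LR and
#' HR grids (both span the same field of view). `pupilRadiusPx()` is the
#' aperture radius `objectiveNA / (wavelength * fourierPitch)` in pixels.
#' `maxIllumNA()` is the illumination NA of the corner LED.
#'
#' @param config an [OpticalConfig-class].
#' @return a numeric scalar.
#' @export
objectPixel <- function(config) config@sensorPixel / config@magnification

#' @rdname objectPixel
#' @export
fourierPitch <- function(config) 1 / (config@lrSide * objectPixel(config))

#' @rdname objectPixel
#' @export
pupilRadiusPx <- function(config)
  config@objectiveNA / (config@wavelength * fourierPitch(config))

#' @rdname objectPixel
#' @export
maxIllumNA <- function(config) {
  dx <- (config@ledCols - 1) / 2 * config@ledPitch
  dy <- (config@ledRows - 1) / 2 * config@ledPitch
  r <- sqrt(dx^2 + dy^2)
  r / sqrt(r^2 + config@ledHeight^2)
}

#' Per-LED illumination geometry
#'
#' Computes, for every LED of the array, the tilt of the illuminating plane
#' wave and the corresponding shift of the sampling window on the
#' high-resolution Fourier grid. Direction sines are obtained from the
#' lateral LED offset and the array height; the spatial tilt frequency is
#' `sin(theta) / wavelength` and is rounded to the nearest integer
#' frequency bin (`pixelShift = round(tiltFrequency / fourierPitch)`).
#' An LED is classified `brightfield` when its illumination NA does not
#' exceed the objective NA, `darkfield` otherwise.
#'
#' @param config an [OpticalConfig-class].
#' @return a data.frame with one row per LED (raster order) and columns
#'   `led`, `row`, `col`, `fx`, `fy` (cycles/um), `shiftX`, `shiftY`
#'   (integer HR-grid bins), `illumNA`, and `regime`.
#' @examples
#' ill <- ledIlluminations(opticalConfig())
#' table(ill$regime)
#' @export
ledIlluminations <- function(config) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  rows <- seq_len(config@ledRows); cols <- seq_len(config@ledCols)
  grid <- expand.grid(col = cols, row = rows)[, c("row", "col")]
  dx <- (grid$col - (config@ledCols + 1) / 2) * config@ledPitch  # mm
  dy <- (grid$row - (config@ledRows + 1) / 2) * config@ledPitch
  h <- config@ledHeight
  rr <- sqrt(dx^2 + dy^2 + h^2)
  sx <- dx / rr; sy <- dy / rr
  fx <- sx / config@wavelength; fy <- sy / config@wavelength
  df <- fourierPitch(config)
  shiftX <- round(fx / df); shiftY <- round(fy / df)
  illumNA <- sqrt(sx^2 + sy^2)
  halfGap <- config@hrSide / 2 - config@lrSide / 2
  if (any(abs(shiftX) > halfGap | abs(shiftY) > halfGap))
    stop("LED geometry pushes a sampling window off the HR grid; ",
         "enlarge hrSide or reduce the LED span")
  data.frame(
    led = seq_len(nrow(grid)), row = grid$row, col = grid$col,
    fx = fx, fy = fy, shiftX = shiftX, shiftY = shiftY,
    illumNA = illumNA,
    regime = ifelse(illumNA <= config@objectiveNA, "brightfield", "darkfield"),
    stringsAsFactors = FALSE)
}

# Update order: illumination NA ascending (centre of Fourier space outward),
# ties broken by (row, col).
naOrder <- function(illuminations)
  order(illuminations$illumNA, illuminations$row, illuminations$col)

#' Sampling window of one illumination on the HR Fourier grid
#'
#' The forward model extracts, for the j-th LED, an `lrSide`-square window
#' of the centred high-resolution spectrum, displaced from the DC bin by
#' that LED's `pixelShift`. `cropSpectrum()` applies the window (the
#' downsampling operator Q_j); `embedSpectrum()` is its adjoint, embedding
#' an LR-grid matrix into an all-zero HR grid. `crop(embed(x)) == x`
#' exactly.
#'
#' @param illumination one row of the [ledIlluminations()] table (or any
#'   list with `shiftX`/`shiftY`).
#' @param config an [OpticalConfig-class].
#' @return `samplingWindow()`: a list with integer index vectors `rows`,
#'   `cols` into the HR grid; `cropSpectrum()`: an lrSide-square matrix;
#'   `embedSpectrum()`: an hrSide-square matrix.
#' @examples
#' cfg <- opticalConfigSmall()
#' win <- samplingWindow(list(shiftX = 0, shiftY = 0), cfg)
#' S <- matrix(rnorm(cfg@hrSide^2), cfg@hrSide)
#' x <- cropSpectrum(S, win)
#' all(cropSpectrum(embedSpectrum(x, win, cfg@hrSide), win) == x)
#' @export
samplingWindow <- function(illumination, config) {
  m <- config@lrSide; n <- config@hrSide
  cy <- n / 2 + 1 + illumination$shiftY
  cx <- n / 2 + 1 + illumination$shiftX
  rows <- (cy - m / 2):(cy + m / 2 - 1)
  cols <- (cx - m / 2):(cx + m / 2 - 1)
  if (rows[1] < 1 || cols[1] < 1 || rows[m] > n || cols[m] > n)
    stop("sampling window falls outside the HR grid")
  structure(list(rows = rows, cols = cols), class = "SpectrumWindow")
}

#' @rdname samplingWindow
#' @param S hrSide-square matrix (a centred spectrum).
#' @param window a window from [samplingWindow()].
#' @export
cropSpectrum <- function(S, window) S[window$rows, window$cols, drop = FALSE]

#' @rdname samplingWindow
#' @param x lrSide-square matrix to embed.
#' @param n side length of the target HR grid.
#' @export
embedSpectrum <- function(x, window, n) {
  out <- matrix(if (is.complex(x)) 0 + 0i else 0, n, n)
  out[window$rows, window$cols] <- x
  out
}

#' Forward intensity model for one illumination
#'
#' Computes the low-resolution intensity image of one LED:
#' `I = |F^H { p * Q_j F u }|^2`, where `F` is the unitary Fourier
#' transform, `Q_j` the sampling window of the illumination and `p` the
#' pupil. Because the transforms are unitary, `sum(I)` equals the power of
#' the filtered spectrum (Parseval).
#'
#' @param u complex object matrix (hrSide square), or an
#'   [FPMGroundTruth-class].
#' @param pupil an [FPMPupil-class].
#' @param window a [samplingWindow()].
#' @return nonnegative lrSide-square intensity matrix.
#' @export
forwardIntensity <- function(u, pupil, window) {
  if (is(u, "FPMGroundTruth")) u <- complexObject(u)
  S <- ftc(u)
  field <- iftc(pupil@values * cropSpectrum(S, window))
  Mod(field)^2
}

#' Amplitude and phase accessors
#'
#' `complexObject()` assembles `amplitude * exp(1i * phase)` from a ground
#' truth; `intensities()`, `illuminations()` and `noiseRecord()` access the
#' corresponding slots of an [FPMMeasurements-class]; `pupilValues()` the
#' complex matrix of a pupil; `reconObject()` and `history()` the recovered
#' object and error history of an [FPMReconstruction-class].
#'
#' @param x the object to access.
#' @return see each description.
#' @export
complexObject <- function(x) {
  stopifnot(is(x, "FPMGroundTruth"))
  x@amplitude * exp(1i * x@phase)
}

#' @rdname complexObject
#' @export
intensities <- function(x) x@intensities

#' @rdname complexObject
#' @export
illuminations <- function(x) x@illuminations

#' @rdname complexObject
#' @export
noiseRecord <- function(x) x@noiseRecord

#' @rdname complexObject
#' @export
pupilValues <- function(x) x@values

#' @rdname complexObject
#' @export
reconObject <- function(x) x@object

#' @rdname complexObject
#' @export
reconHistory <- function(x) x@history

#' Simulate a full FPM measurement stack
#'
#' Runs the forward model over every LED of the array, normalizes the stack
#' so that the brightest brightfield image has mean intensity 1 (the scale
#' on which the darkfield noise threshold of the noise models is defined),
#' and optionally injects noise. Fully reproducible for a given `seed`.
#'
#' @param config an [OpticalConfig-class].
#' @param truth an [FPMGroundTruth-class] on the HR grid.
#' @param pupil an [FPMPupil-class]; defaults to the ideal (aberration-free)
#'   pupil of `config`.
#' @param noise list describing the noise model: `list(model = "none")`
#'   (default), `list(model = "gaussian", level = , threshold = )` or
#'   `list(model = "poisson", sigma = , threshold = )`.
#' @param seed integer seed for the noise draw (ignored for "none").
#' @return an [FPMMeasurements-class].
#' @examples
#' cfg <- opticalConfigSmall(lrSide = 16, hrSide = 48, ledRows = 3, ledCols = 3)
#' ms <- simulateDataset(cfg, syntheticGroundTruth(cfg, seed = 1))
#' dim(intensities(ms))
#' @export
simulateDataset <- function(config, truth, pupil = makePupil(config),
                            noise = list(model = "none"), seed = NULL) {
  ill <- ledIlluminations(config)
  m <- config@lrSide
  stopifnot(nrow(truth@amplitude) == config@hrSide)
  S <- ftc(complexObject(truth))
  I <- array(0, c(m, m, nrow(ill)))
  for (j in seq_len(nrow(ill))) {
    win <- samplingWindow(ill[j, ], config)
    I[, , j] <- Mod(iftc(pupil@values * cropSpectrum(S, win)))^2
  }
  bf <- which(ill$regime == "brightfield")
  means <- apply(I[, , bf, drop = FALSE], 3, mean)
  I <- I / max(means)
  ms <- new("FPMMeasurements", intensities = I, illuminations = ill,
            config = config,
            noiseRecord = list(model = "none", level = 0, seed = NULL,
                               affected = integer()))
  model <- if (is.null(noise$model)) "none" else noise$model
  thr <- if (is.null(noise$threshold)) 0.2 else noise$threshold
  switch(model,
    none = ms,
    gaussian = addGaussianNoise(ms, level = noise$level, threshold = thr,
                                seed = seed),
    poisson = addPoissonNoise(ms, sigma = noise$sigma, threshold = thr,
                              seed = seed),
    stop("unknown noise model: ", model))
}
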