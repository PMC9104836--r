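#' @import methods
NULL

#' Optical configuration of an FPM acquisition
#'
#' Describes the imaging geometry and the sampling grids of a Fourier
#' ptychographic microscope: objective, sensor, LED-array illumination, and
#' the low-resolution (measurement) and high-resolution (reconstruction)
#' pixel grids. All lengths carry the units stated for each slot.
#'
#' @slot wavelength illumination wavelength in micrometres.
#' @slot magnification objective magnification (dimensionless).
#' @slot objectiveNA numerical aperture of the objective, in (0, 1).
#' @slot sensorPixel physical sensor pixel pitch in micrometres.
#' @slot ledRows,ledCols LED-array dimensions.
#' @slot ledPitch centre-to-centre LED spacing in millimetres.
#' @slot ledHeight LED-array height above the sample in millimetres.
#' @slot lrSide side length (pixels) of the low-resolution measurement grid.
#' @slot hrSide side length (pixels) of the high-resolution reconstruction grid.
#'
#' @seealso [opticalConfig()] for the user-facing constructor,
#'   [objectPixel()], [fourierPitch()], [pupilRadiusPx()] for derived
#'   quantities.
#' @export
setClass("OpticalConfig",
  representation(
    wavelength = "numeric", magnification = "numeric",
    objectiveNA = "numeric", sensorPixel = "numeric",
    ledRows = "numeric", ledCols = "numeric",
    ledPitch = "numeric", ledHeight = "numeric",
    lrSide = "numeric", hrSide = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  scal <- function(x) length(x) == 1L && is.finite(x)
  for (nm in slotNames(object))
    if (!scal(slot(object, nm))) msg <- c(msg, paste0(nm, " must be a finite scalar"))
  if (length(msg)) return(msg)
  if (object@wavelength <= 0) msg <- c(msg, "wavelength must be positive")
  if (object@objectiveNA <= 0 || object@objectiveNA >= 1)
    msg <- c(msg, "objectiveNA must lie in (0, 1)")
  if (object@magnification <= 0) msg <- c(msg, "magnification must be positive")
  if (object@sensorPixel <= 0) msg <- c(msg, "sensorPixel must be positive")
  if (object@ledPitch <= 0 || object@ledHeight <= 0)
    msg <- c(msg, "LED pitch and height must be positive")
  if (object@ledRows < 1 || object@ledCols < 1 ||
      object@ledRows != round(object@ledRows) || object@ledCols != round(object@ledCols))
    msg <- c(msg, "ledRows/ledCols must be positive integers")
  if (object@lrSide != round(object@lrSide) || object@hrSide != round(object@hrSide) ||
      object@lrSide %% 2 != 0 || object@hrSide %% 2 != 0)
    msg <- c(msg, "lrSide and hrSide must be even integers")
  else if (object@hrSide < object@lrSide)
    msg <- c(msg, "hrSide must be at least lrSide")
  if (length(msg)) msg else TRUE
})

#' Complex pupil function on the low-resolution Fourier grid
#'
#' The objective's coherent transfer function: a circular aperture whose
#' interior phase encodes aberrations as a Zernike expansion. Modulus is 1
#' inside the aperture and exactly 0 outside.
#'
#' @slot values complex matrix (lrSide x lrSide), centred Fourier grid.
#' @slot mask logical matrix, the circular aperture support.
#' @slot zernike numeric vector of Noll-ordered Zernike coefficients
#'   (radians of phase) used to build the aberration, if any.
#'
#' @seealso [makePupil()]
#' @export
setClass("FPMPupil",
  representation(values = "matrix", mask = "matrix", zernike = "numeric")
)

setValidity("FPMPupil", function(object) {
  v <- object@values; m <- object@mask
  if (!is.complex(v)) return("values must be a complex matrix")
  if (!is.logical(m) || !identical(dim(m), dim(v)))
    return("mask must be a logical matrix with the same dimensions as values")
  if (any(Mod(v[!m]) > 0)) return("pupil must vanish outside the aperture mask")
  TRUE
})

#' Ground-truth complex object for simulation
#'
#' Amplitude (nonnegative transmittance) and phase (radians, wrapped to
#' (-pi, pi]) images on the high-resolution grid; the complex object is
#' `amplitude * exp(1i * phase)`.
#'
#' @slot amplitude nonnegative numeric matrix (hrSide x hrSide).
#' @slot phase numeric matrix of phase values in radians.
#'
#' @seealso [syntheticGroundTruth()], [complexObject()]
#' @export
setClass("FPMGroundTruth",
  representation(amplitude = "matrix", phase = "matrix")
)

setValidity("FPMGroundTruth", function(object) {
  a <- object@amplitude; p <- object@phase
  if (!identical(dim(a), dim(p))) return("amplitude and phase dimensions differ")
  if (any(a < 0)) return("amplitude must be nonnegative")
  if (any(p <= -pi - 1e-12 | p > pi + 1e-12))
    return("phase must be wrapped to (-pi, pi]")
  TRUE
})

#' A stack of low-resolution intensity measurements
#'
#' One intensity image per LED, together with the illumination table, the
#' optical configuration that produced the stack, and a record of any noise
#' injected by the simulator.
#'
#' @slot intensities numeric array, lrSide x lrSide x nLED, elementwise >= 0.
#' @slot illuminations data.frame of per-LED geometry as returned by
#'   [ledIlluminations()], in the same order as the stack.
#' @slot config the [OpticalConfig-class] used.
#' @slot noiseRecord list with elements `model` ("none", "gaussian" or
#'   "poisson"), `level`, `seed` and `affected` (indices of noisy frames).
#'
#' @seealso [simulateDataset()], [addGaussianNoise()], [addPoissonNoise()]
#' @export
setClass("FPMMeasurements",
  representation(intensities = "array", illuminations = "data.frame",
                 config = "OpticalConfig", noiseRecord = "list")
)

setValidity("FPMMeasurements", function(object) {
  I <- object@intensities
  if (length(dim(I)) != 3L) return("intensities must be a 3-d array")
  m <- object@config@lrSide
  if (dim(I)[1] != m || dim(I)[2] != m)
    return("intensity frames must be lrSide x lrSide")
  if (dim(I)[3] != nrow(object@illuminations))
    return("stack depth must match the illumination table")
  if (any(I < 0)) return("intensities must be nonnegative")
  aff <- object@noiseRecord$affected
  if (!is.null(aff) && length(aff) &&
      (any(aff < 1) || any(aff > dim(I)[3])))
    return("noiseRecord$affected out of range")
  TRUE
})

#' Result of an FPM reconstruction
#'
#' Holds the recovered complex object on the high-resolution grid, the
#' recovered pupil, and the solver's per-iteration error history.
#'
#' @slot object complex matrix (hrSide x hrSide), the recovered object.
#' @slot pupil the recovered [FPMPupil-class].
#' @slot history data.frame with columns `iteration`, `Ep` and (for ADMM)
#'   `Ed`: normalized primal/dual error metrics per iteration.
#' @slot iterations number of iterations actually performed.
#' @slot stopReason character: "tolerance", "maxIter" or a diagnostic.
#' @slot solver character: "admm", "gn" or "mpie".
#' @slot params the parameter list the solver ran with.
#'
#' @seealso [fpmADMM()], [fpmGaussNewton()], [fpmMPIE()],
#'   [evaluateReconstruction()]
#' @export
setClass("FPMReconstruction",
  representation(object = "matrix", pupil = "FPMPupil", history = "data.frame",
                 iterations = "numeric", stopReason = "character",
                 solver = "character", params = "list")
)

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  wavelength: %g um   objective: %gx / NA %g\n",
              object@wavelength, object@magnification, object@objectiveNA))
  cat(sprintf("  sensor pixel: %g um  (object plane %g um)\n",
              object@sensorPixel, objectPixel(object)))
  cat(sprintf("  LED array: %d x %d, pitch %g mm, height %g mm\n",
              as.integer(object@ledRows), as.integer(object@ledCols),
              object@ledPitch, object@ledHeight))
  cat(sprintf("  grids: %d x %d (LR) -> %d x %d (HR)\n",
              as.integer(object@lrSide), as.integer(object@lrSide),
              as.integer(object@hrSide), as.integer(object@hrSide)))
})

setMethod("show", "FPMPupil", function(object) {
  cat(sprintf("FPMPupil: %d x %d grid, aperture %d px, %s\n",
              nrow(object@values), ncol(object@values), sum(object@mask),
              if (length(object@zernike) && any(object@zernike != 0))
                sprintf("%d Zernike term(s)", length(object@zernike))
              else "aberration-free"))
})

setMethod("show", "FPMGroundTruth", function(object) {
  cat(sprintf("FPMGroundTruth: %d x %d, amplitude [%.3g, %.3g], phase [%.3g, %.3g] rad\n",
              nrow(object@amplitude), ncol(object@amplitude),
              min(object@amplitude), max(object@amplitude),
              min(object@phase), max(object@phase)))
})

setMethod("show", "FPMMeasurements", function(object) {
  d <- dim(object@intensities)
  nr <- object@noiseRecord
  cat(sprintf("FPMMeasurements: %d frames of %d x %d, noise: %s\n",
              d[3], d[1], d[2],
              if (is.null(nr$model) || nr$model == "none") "none"
              else sprintf("%s (level %g, %d frames)", nr$model, nr$level,
                           length(nr$affected))))
})

setMethod("show", "FPMReconstruction", function(object) {
  cat(sprintf("FPMReconstruction [%s]: %d x %d object, %d iteration(s), stop: %s\n",
              object@solver, nrow(object@object), ncol(object@object),
              as.integer(object@iterations), object@stopReason))
  if (nrow(object@history)) {
    h <- object@history[nrow(object@history), ]
    cat(sprintf("  final Ep = %.4g%s\n", h$Ep,
                if (!is.null(h$Ed) && is.finite(h$Ed))
                  sprintf(", Ed = %.4g", h$Ed) else ""))
  }
})
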