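# Structural similarity and reconstruction evaluation. Phase retrieval
# recovers the object only up to a global phase, a global intensity scale
# and (in general) a translation, so evaluation aligns first and computes
# SSIM on the aligned, nonnegative images.

gaussKernel1d <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable "valid" convolution by banded-matrix multiplication.
sepConvValid <- function(x, g) {
  n1 <- nrow(x); n2 <- ncol(x); k <- length(g)
  stopifnot(n1 >= k, n2 >= k)
  band <- function(n) {
    B <- matrix(0, n - k + 1, n)
    for (i in seq_len(n - k + 1)) B[i, i:(i + k - 1)] <- g
    B
  }
  band(n1) %*% x %*% t(band(n2))
}

#' Structural similarity index between two images
#'
#' Computes SSIM,
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`,
#' with `C1 = (k1 L)^2`, `C2 = (k2 L)^2` on the dynamic range `L`. The
#' `"windowed"` method (default) evaluates the statistics under an 11 x 11
#' Gaussian window (sigma 1.5) and averages the local map — the standard
#' formulation; `"global"` evaluates the formula once over the whole image.
#' Symmetric in its arguments; equals 1 iff the images are structurally
#' identical.
#'
#' @param x,y nonnegative numeric matrices of identical dimensions,
#'   already aligned (see [alignForEval()]).
#' @param method `"windowed"` or `"global"`.
#' @param dynamicRange the range `L`; defaults to the joint data range
#'   (1 when both images are constant).
#' @param k1,k2 stabilization constants (conventional 0.01 / 0.03).
#' @param windowSize,windowSigma Gaussian window parameters for the
#'   windowed method.
#' @return a similarity value in [0, 1] for nonnegative inputs.
#' @examples
#' x <- matrix(runif(64), 8)
#' fpmSSIM(x, x)                       # exactly 1
#' fpmSSIM(x, 1 - x) < 1
#' @export
fpmSSIM <- function(x, y, method = c("windowed", "global"),
                    dynamicRange = NULL, k1 = 0.01, k2 = 0.03,
                    windowSize = 11, windowSigma = 1.5) {
  method <- match.arg(method)
  if (!identical(dim(x), dim(y))) stop("image dimensions differ")
  if (is.null(dynamicRange)) {
    dynamicRange <- diff(range(c(x, y)))
    if (dynamicRange == 0) dynamicRange <- 1
  }
  C1 <- (k1 * dynamicRange)^2
  C2 <- (k2 * dynamicRange)^2
  if (method == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    vxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * vxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  g <- gaussKernel1d(windowSize, windowSigma)
  mx <- sepConvValid(x, g); my <- sepConvValid(y, g)
  vx <- sepConvValid(x * x, g) - mx^2
  vy <- sepConvValid(y * y, g) - my^2
  vxy <- sepConvValid(x * y, g) - mx * my
  ssimMap <- ((2 * mx * my + C1) * (2 * vxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(ssimMap)
}

# Integer translation maximizing circular cross-correlation, via FFT.
estimateShift <- function(a, b) {
  X <- stats::fft(a) * Conj(stats::fft(b))
  cc <- Re(stats::fft(X, inverse = TRUE))
  idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- idx - 1L
  n <- dim(a)
  sh <- ifelse(sh > n / 2, sh - n, sh)
  as.integer(sh)
}

circShift <- function(x, sh) {
  n <- dim(x)
  idx1 <- ((seq_len(n[1]) - 1 - sh[1]) %% n[1]) + 1
  idx2 <- ((seq_len(n[2]) - 1 - sh[2]) %% n[2]) + 1
  x[idx1, idx2, drop = FALSE]
}

#' Align a reconstruction to its ground truth for evaluation
#'
#' Removes the ambiguities inherent to phase retrieval before computing
#' SSIM: integer translation (by FFT cross-correlation of the moduli),
#' global intensity scale for amplitude images (`type = "amplitude"`,
#' least-squares scale), global phase offset for phase images
#' (`type = "phase"`, mean offset, result re-wrapped), or, for complex
#' objects (`type = "complex"`), a single complex factor removing both at
#' once.
#'
#' @param recon reconstructed image (numeric, or complex for
#'   `type = "complex"`).
#' @param truth reference image of the same kind and dimensions.
#' @param type `"amplitude"`, `"phase"` or `"complex"`.
#' @param translate logical; also remove an integer translation.
#' @return the aligned reconstruction.
#' @export
alignForEval <- function(recon, truth,
                         type = c("amplitude", "phase", "complex"),
                         translate = TRUE) {
  type <- match.arg(type)
  if (!identical(dim(recon), dim(truth))) stop("image dimensions differ")
  if (translate) {
    sh <- estimateShift(Mod(truth), Mod(recon))
    recon <- circShift(recon, sh)
  }
  switch(type,
    amplitude = {
      c0 <- sum(recon * truth) / sum(recon^2)
      recon * c0
    },
    phase = wrapPhase(recon + mean(wrapPhase(truth - recon))),
    complex = {
      c0 <- sum(Conj(recon) * truth) / sum(Mod(recon)^2)
      recon * c0
    })
}

#' Evaluate a reconstruction against the ground truth
#'
#' Complex-aligns the recovered object to the truth (global phase and
#' scale, integer translation), then reports the windowed SSIM of the
#' amplitude images and of the phase images. Phase maps are shifted by a
#' common constant into the nonnegative range before SSIM, as the index is
#' defined for nonnegative images.
#'
#' @param recon an [FPMReconstruction-class] (or a complex object matrix).
#' @param truth an [FPMGroundTruth-class].
#' @param ... passed to [fpmSSIM()].
#' @return a list with `amplitudeSSIM` and `phaseSSIM`.
#' @export
evaluateReconstruction <- function(recon, truth, ...) {
  u <- if (is(recon, "FPMReconstruction")) recon@object else recon
  ut <- complexObject(truth)
  u <- alignForEval(u, ut, type = "complex")
  ampSSIM <- fpmSSIM(Mod(u), truth@amplitude, ...)
  phR <- Arg(u); phT <- truth@phase
  shift <- min(phR, phT)
  phaseSSIM <- fpmSSIM(phR - shift, phT - shift, ...)
  list(amplitudeSSIM = ampSSIM, phaseSSIM = phaseSSIM)
}

#' Correlation of recovered and reference pupil phase
#'
#' Pearson correlation of the phase values inside the aperture mask, after
#' removing the global phase (piston) of each pupil and wrapping. Used to
#' quantify aberration recovery.
#'
#' @param pupilA,pupilB [FPMPupil-class] objects on the same grid.
#' @return correlation in [-1, 1].
#' @export
pupilPhaseCorrelation <- function(pupilA, pupilB) {
  mask <- pupilA@mask & pupilB@mask
  phA <- depiston(pupilA@values, mask)
  phB <- depiston(pupilB@values, mask)
  stats::cor(phA[mask], phB[mask])
}

depiston <- function(values, mask) {
  piston <- Arg(sum(values[mask]))
  wrapPhase(Arg(values * exp(-1i * piston)))
}

#' Extract a horizontal line profile
#'
#' Returns the pixel values along one image row, for comparing noise
#' fluctuation across reconstructions, together with the standard
#' deviation over a designated background segment of that row.
#'
#' @param image numeric matrix.
#' @param row row index.
#' @param backgroundCols column indices of the background segment
#'   (default: the whole row).
#' @return list with `values` (the row) and `backgroundSD`.
#' @examples
#' img <- matrix(0, 8, 8); img[4, 6] <- 5
#' lineProfile(img, 4)$values
#' @export
lineProfile <- function(image, row, backgroundCols = seq_len(ncol(image))) {
  stopifnot(row >= 1, row <= nrow(image))
  vals <- image[row, ]
  list(values = vals, backgroundSD = stats::sd(vals[backgroundCols]))
}
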