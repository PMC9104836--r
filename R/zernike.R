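# Zernike polynomials in Noll ordering, used to paint aberration phase on
# the pupil. Noll normalization: sqrt(n+1) for m = 0, sqrt(2(n+1)) otherwise,
# even j -> cosine terms, odd j -> sine terms.

nollToNM <- function(j) {
  stopifnot(j >= 1)
  n <- 0; k <- j
  while (k > n + 1) { k <- k - (n + 1); n <- n + 1 }
  mAbs <- if (n %% 2 == 0) 2 * floor(k / 2) else 2 * floor((k - 1) / 2) + 1
  m <- if (mAbs == 0) 0 else if (j %% 2 == 0) mAbs else -mAbs
  c(n = n, m = m)
}

zernikeRadial <- function(n, mAbs, rho) {
  out <- 0
  for (s in 0:((n - mAbs) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + mAbs) / 2 - s) *
         factorial((n - mAbs) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

#' Zernike aberration phase on the pupil grid
#'
#' Evaluates a Noll-ordered Zernike expansion on the unit disk inscribed in
#' the pupil aperture. Coefficients are in radians; Noll mode 1 is piston,
#' 2-3 tilt, 4 defocus, 5-6 astigmatism, 7-8 coma, 11 primary spherical.
#'
#' @param coefficients numeric vector; element j multiplies Noll mode j.
#' @param rho matrix of radial coordinates normalized to the aperture
#'   radius (1 at the aperture edge).
#' @param theta matrix of azimuthal angles (radians).
#' @return matrix of phase values (radians); zero where `rho > 1`.
#' @export
zernikePhase <- function(coefficients, rho, theta) {
  stopifnot(all(is.finite(coefficients)))
  phase <- matrix(0, nrow(rho), ncol(rho))
  inside <- rho <= 1
  for (j in seq_along(coefficients)) {
    c_j <- coefficients[j]
    if (c_j == 0) next
    nm <- nollToNM(j)
    n <- nm["n"]; m <- nm["m"]
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    rad <- zernikeRadial(n, abs(m), rho)
    ang <- if (m == 0) 1 else if (m > 0) cos(m * theta) else sin(-m * theta)
    phase <- phase + c_j * norm * rad * ang
  }
  phase[!inside] <- 0
  phase
}

#' Construct a pupil function
#'
#' Builds the circular-aperture pupil on the low-resolution Fourier grid:
#' modulus 1 inside a disk of radius `objectiveNA / (wavelength *
#' fourierPitch)` pixels, 0 outside, with interior phase given by a Zernike
#' expansion. With no coefficients the pupil is the binary aperture mask.
#'
#' @param config an [OpticalConfig-class].
#' @param zernike numeric vector of Noll-ordered coefficients (radians);
#'   empty for an aberration-free pupil.
#' @return an [FPMPupil-class].
#' @examples
#' p <- makePupil(opticalConfig())
#' sum(p@mask)                    # pixels inside the aperture
#' pAb <- makePupil(opticalConfig(), zernike = c(0, 0, 0, 0.5))  # defocus
#' @export
makePupil <- function(config, zernike = numeric()) {
  stopifnot(all(is.finite(zernike)))
  m <- config@lrSide
  R <- pupilRadiusPx(config)
  if (R >= m / 2)
    stop(sprintf("pupil radius (%.1f px) exceeds the LR grid half-width (%d px)",
                 R, m / 2))
  u <- ((1:m) - (m / 2 + 1))
  X <- matrix(u, m, m, byrow = TRUE)   # column index -> x
  Y <- matrix(u, m, m)                 # row index    -> y
  r <- sqrt(X^2 + Y^2)
  mask <- r <= R
  vals <- matrix(0 + 0i, m, m)
  if (length(zernike) && any(zernike != 0)) {
    phase <- zernikePhase(zernike, r / R, atan2(Y, X))
    vals[mask] <- exp(1i * phase[mask])
  } else {
    vals[mask] <- 1 + 0i
  }
  new("FPMPupil", values = vals, mask = mask,
      zernike = as.numeric(zernike))
}
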