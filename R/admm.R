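# Scaled-form ADMM for blind FPM phase retrieval.
#
# The splitting introduces per-illumination variables q_j = p * Q_j s and
# scaled multipliers w_j = lambda_j / alpha. One iteration performs, in
# batch: the relaxed magnitude projection on every q_j, the closed-form
# Tikhonov-regularized solve for the object spectrum s, the per-pixel
# ridge solve for the pupil p, and the multiplier ascent on w_j.
#
# Measured intensities enter as amplitudes A_j = sqrt(I_j), rescaled by
# hrSide/lrSide so that a flat unit-transmittance object produces
# unit-scale model fields under the unitary transform convention; this
# keeps the flat-field anchor delta commensurate with the data.

#' ADMM solver parameters
#'
#' Defaults follow the suggested ranges for the method: penalty
#' `alpha = 0.5`, pupil regularizer `beta = 1000`, Tikhonov weight
#' `gamma = 0.3`, multiplier step `eta = 1`, 100 iterations.
#'
#' @param alpha augmented-Lagrangian penalty (> 0). Controls the relaxation
#'   of the magnitude projection: `alpha = 0` enforces measured amplitudes
#'   exactly, large `alpha` freezes `q`.
#' @param beta pupil ridge regularizer (> 0); larger values slow the pupil
#'   update.
#' @param gamma Tikhonov weight (>= 0) anchoring the object spectrum to the
#'   flat-field spectrum `delta` (weak-phase prior).
#' @param eta multiplier step size (> 0).
#' @param epsTol stopping tolerance on the relative change of both
#'   normalized error metrics; `Inf` stops after one iteration.
#' @param maxIter iteration cap.
#' @param initMode `"ones"` (flat-field start, the default that works best
#'   for this solver) or `"upsampled"` (Fourier-embedded centre-LED image).
#' @param betaScale `"dft"` (default) interprets `beta` on the power scale
#'   of an unnormalized DFT — the scale on which the conventional value
#'   1000 is quoted — and divides by `lrSide^2` to obtain the equivalent
#'   ridge under this package's unitary transforms; `"raw"` applies `beta`
#'   to the unitary-scale spectra as given.
#' @param schedule `"batch"` (all q_j, then s, p, w: the parallel form) or
#'   `"sequential"` (nests the s/p updates inside the per-LED loop).
#' @param order `"na"` (illumination-NA ascending) or `"raster"`.
#' @return a named list of class `"admmParams"`.
#' @export
admmParams <- function(alpha = 0.5, beta = 1000, gamma = 0.3, eta = 1,
                       epsTol = 1e-3, maxIter = 100,
                       initMode = c("ones", "upsampled"),
                       schedule = c("batch", "sequential"),
                       order = c("na", "raster"),
                       betaScale = c("dft", "raw")) {
  stopifnot(alpha >= 0, beta > 0, eta >= 0, gamma >= 0, maxIter >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, eta = eta,
                 epsTol = epsTol, maxIter = maxIter,
                 initMode = match.arg(initMode),
                 schedule = match.arg(schedule),
                 order = match.arg(order),
                 betaScale = match.arg(betaScale)),
            class = "admmParams")
}

# Effective pupil ridge: `beta` is quoted on the unnormalized-DFT power
# scale (where its conventional value is ~1000); unitary spectra carry
# 1/m^2 of that power, so the equivalent ridge divides by lrSide^2.
pupilRidge <- function(params, m) {
  if (identical(params$betaScale, "raw")) params$beta else params$beta / m^2
}

# Measured amplitudes on the model scale (see header note).
measuredAmplitudes <- function(ms) {
  scale <- ms@config@hrSide / ms@config@lrSide
  sqrt(ms@intensities) * scale
}

# Fourier-embed the centre-LED amplitude as an HR spectrum whose model
# field reproduces that amplitude exactly.
upsampledInit <- function(A, ill, config) {
  centre <- which(ill$shiftX == 0 & ill$shiftY == 0)[1]
  if (is.na(centre)) centre <- which.min(ill$illumNA)
  win <- samplingWindow(ill[centre, ], config)
  embedSpectrum(ftc(A[, , centre]), win, config@hrSide)
}

#' Initialize the ADMM state
#'
#' Builds the starting iterate: object spectrum `s0` from a flat all-ones
#' field (or the upsampled centre-LED image), `q_j0 = p0 * Q_j s0`
#' (so the primal splitting residual starts at exactly zero), multipliers
#' `w_j0 = 0`, and the flat-field reference spectrum `delta`.
#'
#' @param ms an [FPMMeasurements-class].
#' @param pupil0 initial [FPMPupil-class] (typically aberration-free).
#' @param params an [admmParams()] list.
#' @return a list (the ADMM state) with elements `s`, `p`, `q`, `w`,
#'   `delta`, `A`, `windows`, `mask`, `k`.
#' @export
admmInitialize <- function(ms, pupil0, params = admmParams()) {
  config <- ms@config
  ill <- ms@illuminations
  if (nrow(ill) == 0) stop("empty measurement set")
  m <- config@lrSide; n <- config@hrSide
  stopifnot(nrow(pupil0@values) == m)
  A <- measuredAmplitudes(ms)
  windows <- lapply(seq_len(nrow(ill)),
                    function(j) samplingWindow(ill[j, ], config))
  delta <- ftc(matrix(1 + 0i, n, n))
  s <- switch(params$initMode,
              ones = delta,
              upsampled = upsampledInit(A, ill, config))
  p <- pupil0@values
  q <- array(0 + 0i, dim(A))
  for (j in seq_along(windows))
    q[, , j] <- p * cropSpectrum(s, windows[[j]])
  list(s = s, p = p, q = q, w = array(0 + 0i, dim(A)),
       delta = delta, A = A, windows = windows, mask = pupil0@mask,
       order = if (params$order == "na") naOrder(ill) else seq_len(nrow(ill)),
       k = 0L)
}

#' One ADMM subproblem update
#'
#' The four closed-form updates of the scaled ADMM iteration. Each takes
#' the state list produced by [admmInitialize()] and returns the updated
#' quantity; [fpmADMM()] wires them into the full loop.
#'
#' `updateQ()` performs the relaxed projection onto the measured-amplitude
#' set for illumination `j`: with `qt = p * Q_j s - w_j` and spatial field
#' `e = F^H qt`, the update is `q <- qt + (F[A_j * e/|e|] - qt)/(1+alpha)`.
#' Pixels with `|e| = 0` take phase 0.
#'
#' `updateS()` solves the Tikhonov-regularized least-squares problem for
#' the object spectrum: elementwise division of the accumulated adjoint
#' numerator by the diagonal denominator `gamma/alpha + sum_j Q_j^T |p|^2`.
#' Bins with a zero denominator (possible only when `gamma = 0` and no
#' window covers them) keep their previous value.
#'
#' `updateP()` solves the per-pixel ridge problem for the pupil,
#' `p <- sum_j conj(Q_j s)(q_j + w_j) / (sum_j |Q_j s|^2 + ridge)`, then
#' re-applies the aperture support mask; the ridge is `beta` itself under
#' `betaScale = "raw"` and `beta / lrSide^2` under the default `"dft"`
#' interpretation (see [admmParams()]).
#'
#' `updateOmega()` is the scaled multiplier ascent
#' `w_j <- w_j + eta (q_j - p * Q_j s)`.
#'
#' @param state the ADMM state list.
#' @param params an [admmParams()] list.
#' @param j illumination index.
#' @return `updateQ`/`updateOmega`: an LR-grid complex matrix;
#'   `updateS`: the HR spectrum; `updateP`: the LR pupil matrix.
#' @export
updateQ <- function(state, params, j) {
  qt <- state$p * cropSpectrum(state$s, state$windows[[j]]) - state$w[, , j]
  e <- iftc(qt)
  unit <- unitPhase(e)
  proj <- ftc(state$A[, , j] * unit)
  if (is.infinite(params$alpha)) qt else qt + (proj - qt) / (1 + params$alpha)
}

# e / |e| with the zero-magnitude convention phase = 0 (unit value 1)
unitPhase <- function(e) {
  mag <- Mod(e)
  zero <- mag == 0
  if (any(zero)) mag[zero] <- 1
  unit <- e / mag
  if (any(zero)) unit[zero] <- 1 + 0i
  unit
}

# Fused q-update used by the solver loop: identical to updateQ (the
# transforms are linear, so blending in the spatial domain commutes with
# blending in Fourier space) but also returns the post-update amplitude
# misfit without a further transform.
updateQFused <- function(state, params, j) {
  qt <- state$p * cropSpectrum(state$s, state$windows[[j]]) - state$w[, , j]
  e <- iftc(qt)
  A <- state$A[, , j]
  eNew <- if (is.infinite(params$alpha)) e else
    e + (A * unitPhase(e) - e) / (1 + params$alpha)
  list(q = ftc(eNew), misfit = sum((Mod(eNew) - A)^2))
}

#' @rdname updateQ
#' @export
updateS <- function(state, params) {
  n <- nrow(state$s)
  ridge <- if (params$alpha > 0) params$gamma / params$alpha else
    if (params$gamma > 0) Inf else 0
  if (is.infinite(ridge)) return(state$delta)
  num <- ridge * state$delta
  den <- matrix(ridge, n, n)
  p2 <- Mod(state$p)^2
  pc <- Conj(state$p)
  for (j in seq_along(state$windows)) {
    win <- state$windows[[j]]
    num[win$rows, win$cols] <- num[win$rows, win$cols] +
      pc * (state$q[, , j] + state$w[, , j])
    den[win$rows, win$cols] <- den[win$rows, win$cols] + p2
  }
  out <- num / pmax(den, .Machine$double.xmin)
  dead <- den == 0
  if (any(dead)) out[dead] <- state$s[dead]
  out
}

#' @rdname updateQ
#' @export
updateP <- function(state, params) {
  m <- nrow(state$p)
  ridge <- pupilRidge(params, m)
  num <- matrix(0 + 0i, m, m)
  den <- matrix(ridge, m, m)
  for (j in seq_along(state$windows)) {
    cj <- cropSpectrum(state$s, state$windows[[j]])
    num <- num + Conj(cj) * (state$q[, , j] + state$w[, , j])
    den <- den + Mod(cj)^2
  }
  out <- num / den
  out[!state$mask] <- 0 + 0i
  out
}

#' @rdname updateQ
#' @export
updateOmega <- function(state, params, j) {
  state$w[, , j] + params$eta *
    (state$q[, , j] - state$p * cropSpectrum(state$s, state$windows[[j]]))
}

#' ADMM residuals and normalized error metrics
#'
#' `admmResiduals()` returns the primal residual in measurement space,
#' `Rp = sum_j || |F^H q_j| - A_j ||^2`, and the dual residual
#' `Rd = sum_j || q_j^k - q_j^{k-1} ||^2` (`NA` before the first completed
#' iteration). `admmErrorMetrics()` normalizes them:
#' `Ep = Rp / sum_j ||A_j||^2` and
#' `Ed = (alpha/eta) Rd / sum_j ||lambda_j||^2` with `lambda_j = alpha w_j`;
#' `Ed` is `NA` while all multipliers are zero.
#'
#' @param state the ADMM state list (with `q`, `A`, `w`).
#' @param qPrev the previous iteration's `q` array, or `NULL`.
#' @param params an [admmParams()] list.
#' @return a list with `Rp`, `Rd` (residuals) or `Ep`, `Ed` (metrics).
#' @export
admmResiduals <- function(state, qPrev = NULL) {
  Rp <- 0
  for (j in seq_len(dim(state$q)[3])) {
    e <- iftc(state$q[, , j])
    Rp <- Rp + sum((Mod(e) - state$A[, , j])^2)
  }
  Rd <- if (is.null(qPrev)) NA_real_ else sum(Mod(state$q - qPrev)^2)
  list(Rp = Rp, Rd = Rd)
}

#' @rdname admmResiduals
#' @export
admmErrorMetrics <- function(state, qPrev = NULL, params = admmParams()) {
  res <- admmResiduals(state, qPrev)
  Ep <- res$Rp / sum(state$A^2)
  lam2 <- params$alpha^2 * sum(Mod(state$w)^2)
  Ed <- if (is.na(res$Rd) || lam2 == 0) NA_real_ else
    (params$alpha / params$eta) * res$Rd / lam2
  list(Ep = Ep, Ed = Ed)
}

relChange <- function(h) {
  # |E^k - E^{k-1}| / E^k over the last two available values; Inf when
  # fewer than two finite values exist (criterion then passes only for an
  # infinite tolerance)
  h <- h[is.finite(h)]
  k <- length(h)
  if (k < 2) return(Inf)
  abs(h[k] - h[k - 1]) / h[k]
}

#' Run the ADMM-FPM solver
#'
#' Iterates the scaled ADMM updates (batch schedule by default: all
#' magnitude projections, then the object solve, the pupil solve, and the
#' multiplier ascent) until both normalized error metrics have stabilized
#' — relative change of `Ep` and of `Ed` both within `epsTol` — or
#' `maxIter` is reached. The dual criterion participates once multipliers
#' are nonzero. A run whose `Ep` exceeds one million times its initial
#' value aborts with a diagnostic error.
#'
#' @param ms an [FPMMeasurements-class].
#' @param pupil0 initial [FPMPupil-class]; defaults to the aberration-free
#'   pupil of the dataset's configuration.
#' @param params an [admmParams()] list.
#' @return an [FPMReconstruction-class]; the spatial object is
#'   `F^H s` and the history holds `Ep`/`Ed` per iteration (iteration 0 is
#'   the initialization's primal error).
#' @examples
#' cfg <- opticalConfigSmall(lrSide = 16, hrSide = 48, ledRows = 3, ledCols = 3)
#' ms <- simulateDataset(cfg, syntheticGroundTruth(cfg, seed = 1))
#' rec <- fpmADMM(ms, params = admmParams(maxIter = 5))
#' rec
#' @export
fpmADMM <- function(ms, pupil0 = makePupil(ms@config),
                    params = admmParams()) {
  state <- admmInitialize(ms, pupil0, params)
  em0 <- admmErrorMetrics(state, NULL, params)
  EpHist <- em0$Ep; EdHist <- NA_real_
  stopReason <- "maxIter"
  k <- 0L
  aNorm <- sum(state$A^2)
  while (k < params$maxIter) {
    k <- k + 1L
    qPrev <- state$q
    if (params$schedule == "batch") {
      misfit <- 0
      for (j in state$order) {
        up <- updateQFused(state, params, j)
        state$q[, , j] <- up$q
        misfit <- misfit + up$misfit
      }
      state$s <- updateS(state, params)
      state$p <- updateP(state, params)
      for (j in state$order) state$w[, , j] <- updateOmega(state, params, j)
      Rd <- sum(Mod(state$q - qPrev)^2)
      lam2 <- params$alpha^2 * sum(Mod(state$w)^2)
      em <- list(Ep = misfit / aNorm,
                 Ed = if (lam2 == 0) NA_real_ else
                   (params$alpha / params$eta) * Rd / lam2)
    } else {
      for (j in state$order) {
        state$q[, , j] <- updateQ(state, params, j)
        state$s <- updateS(state, params)
        state$p <- updateP(state, params)
        state$w[, , j] <- updateOmega(state, params, j)
      }
      em <- admmErrorMetrics(state, qPrev, params)
    }
    EpHist <- c(EpHist, em$Ep); EdHist <- c(EdHist, em$Ed)
    if (em$Ep > 1e6 * max(EpHist[1], .Machine$double.xmin))
      stop(sprintf(
        "ADMM diverged: Ep = %.3g at iteration %d (initial %.3g)",
        em$Ep, k, EpHist[1]))
    if (relChange(EpHist) <= params$epsTol &&
        relChange(EdHist) <= params$epsTol) {
      stopReason <- "tolerance"
      break
    }
  }
  u <- iftc(state$s)
  pupil <- new("FPMPupil", values = state$p,
               mask = state$mask, zernike = numeric())
  new("FPMReconstruction", object = u, pupil = pupil,
      history = data.frame(iteration = 0:k, Ep = EpHist, Ed = EdHist),
      iterations = k, stopReason = stopReason, solver = "admm",
      params = unclass(params))
}
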