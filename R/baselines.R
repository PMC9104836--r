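# Comparison solvers sharing the forward model, dataset container and
# error metric with the ADMM solver: a sequential second-order
# Gauss-Newton sweep with self-adaptive (halving) step sizes, and a
# momentum-accelerated ptychographic iterative engine (mPIE) with
# rPIE-style regularized denominators.

#' Gauss-Newton solver parameters
#'
#' @param alpha0,beta0 initial object/pupil step sizes (> 0).
#' @param epsStep step-halving threshold: the step is halved whenever the
#'   normalized error metric rises by more than `epsStep` relative terms
#'   between sweeps, and kept otherwise.
#' @param epsTol stopping tolerance on the relative change of the error
#'   metric (shared stopping rule across solvers).
#' @param maxIter sweep cap.
#' @param order `"na"` or `"raster"` update sequence.
#' @param initMode `"upsampled"` (Fourier-upsampled centre-LED image, the
#'   conventional warm start for this solver) or `"ones"`.
#' @return a named list of class `"gnParams"`.
#' @export
gnParams <- function(alpha0 = 1, beta0 = 1, epsStep = 0.01,
                     epsTol = 1e-3, maxIter = 100,
                     order = c("na", "raster"),
                     initMode = c("upsampled", "ones")) {
  stopifnot(alpha0 > 0, beta0 > 0, is.numeric(epsStep), maxIter >= 0)
  structure(list(alpha0 = alpha0, beta0 = beta0, epsStep = epsStep,
                 epsTol = epsTol, maxIter = maxIter,
                 order = match.arg(order), initMode = match.arg(initMode)),
            class = "gnParams")
}

#' mPIE solver parameters
#'
#' Parameters are namespaced to this solver (the object-step regularizer
#' `alpha` is unrelated to the ADMM penalty of the same letter).
#'
#' @param alpha rPIE object-denominator mixing weight in (0, 1].
#' @param beta rPIE pupil-denominator mixing weight in (0, 1].
#' @param gamma friction applied to the momentum step.
#' @param etaObj,etaPupil momentum decay weights for object and pupil
#'   velocity.
#' @param tPupil global illumination-update index at which pupil updates
#'   begin (the object updates from the very first).
#' @param epsTol,maxIter stopping tolerance and sweep cap as in
#'   [gnParams()].
#' @param order `"na"` or `"raster"` update sequence.
#' @return a named list of class `"mpieParams"`.
#' @export
mpieParams <- function(alpha = 0.1, beta = 0.8, gamma = 1,
                       etaObj = 0.9, etaPupil = 0.3, tPupil = 15,
                       epsTol = 1e-3, maxIter = 100,
                       order = c("na", "raster")) {
  stopifnot(alpha > 0, alpha <= 1, beta > 0, beta <= 1,
            gamma >= 0, etaObj >= 0, etaPupil >= 0, tPupil >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 etaObj = etaObj, etaPupil = etaPupil, tPupil = tPupil,
                 epsTol = epsTol, maxIter = maxIter,
                 order = match.arg(order)),
            class = "mpieParams")
}

#' Self-adaptive step-size rule
#'
#' Halves the step whenever the normalized error metric grew by more than
#' `eps` in signed relative terms, `(E^k - E^{k-1}) / E^k > eps`, and keeps
#' it otherwise. Applied to both the object and pupil steps of the
#' Gauss-Newton solver after every sweep.
#'
#' @param eHistory numeric vector of error-metric values (needs >= 2).
#' @param alphaPrev current step size.
#' @param eps threshold (a constant much smaller than 1; 0.01 works well).
#' @return the next step size.
#' @examples
#' adaptStep(c(0.5, 0.4), 1, 0.01)   # error fell: step kept
#' adaptStep(c(0.4, 0.5), 1, 0.01)   # error rose 20%: step halved
#' @export
adaptStep <- function(eHistory, alphaPrev, eps) {
  k <- length(eHistory)
  stopifnot(k >= 2)
  if ((eHistory[k] - eHistory[k - 1]) / eHistory[k] > eps)
    alphaPrev / 2 else alphaPrev
}

# Shared per-illumination forward pass: returns the modelled LR spectrum,
# its spatial field, and the spectrum correction after the magnitude
# replacement. Also accumulates the squared amplitude misfit.
sweepStep <- function(s, p, A_j, win) {
  Sw <- cropSpectrum(s, win)
  Psi <- p * Sw
  psi <- iftc(Psi)
  dPsi <- ftc(A_j * unitPhase(psi)) - Psi
  list(Sw = Sw, dPsi = dPsi, misfit = sum((Mod(psi) - A_j)^2))
}

checkDiverged <- function(E, E0, solver, k) {
  if (is.finite(E) && E > 1e6 * max(E0, .Machine$double.xmin))
    stop(sprintf("%s diverged: E = %.3g at iteration %d (initial %.3g)",
                 solver, E, k, E0))
}

#' Sequential Gauss-Newton reconstruction with self-adaptive steps
#'
#' Sweeps the illuminations in NA-ascending order, applying the
#' second-order pupil-weighted quotient updates to the object spectrum
#' window and the pupil (both normalized by the maximum modulus of the
#' weighting function), and after each sweep adapts the step sizes with
#' [adaptStep()] on the normalized amplitude error metric. Stops when the
#' relative change of the error metric is within `epsTol`.
#'
#' @param ms an [FPMMeasurements-class].
#' @param pupil0 initial [FPMPupil-class].
#' @param params a [gnParams()] list.
#' @return an [FPMReconstruction-class]; the history additionally records
#'   the per-sweep step sizes `alphaStep`/`betaStep`.
#' @export
fpmGaussNewton <- function(ms, pupil0 = makePupil(ms@config),
                           params = gnParams()) {
  config <- ms@config
  ill <- ms@illuminations
  A <- measuredAmplitudes(ms)
  windows <- lapply(seq_len(nrow(ill)),
                    function(j) samplingWindow(ill[j, ], config))
  ord <- if (params$order == "na") naOrder(ill) else seq_len(nrow(ill))
  n <- config@hrSide
  s <- if (params$initMode == "upsampled")
    upsampledInit(A, ill, config) else ftc(matrix(1 + 0i, n, n))
  p <- pupil0@values; mask <- pupil0@mask
  aNorm <- sum(A^2)
  d1 <- 1e-10; d2reg <- 1e-10
  alphaK <- params$alpha0; betaK <- params$beta0
  EHist <- numeric(); aHist <- numeric(); bHist <- numeric()
  stopReason <- "maxIter"; k <- 0L
  while (k < params$maxIter) {
    k <- k + 1L
    misfit <- 0
    for (j in ord) {
      st <- sweepStep(s, p, A[, , j], windows[[j]])
      misfit <- misfit + st$misfit
      pm <- max(Mod(p))
      pa <- Mod(p)
      sNew <- st$Sw + alphaK * pa * Conj(p) * st$dPsi /
        (pm * (pa^2 + d1))
      sm <- max(Mod(st$Sw))
      sa <- Mod(st$Sw)
      p <- p + betaK * sa * Conj(st$Sw) * st$dPsi /
        (sm * (sa^2 + d2reg * sm^2))
      p[!mask] <- 0 + 0i
      win <- windows[[j]]
      s[win$rows, win$cols] <- sNew
    }
    EHist <- c(EHist, misfit / aNorm)
    aHist <- c(aHist, alphaK); bHist <- c(bHist, betaK)
    checkDiverged(EHist[k], EHist[1], "Gauss-Newton", k)
    if (length(EHist) >= 2) {
      alphaK <- adaptStep(EHist, alphaK, params$epsStep)
      betaK <- adaptStep(EHist, betaK, params$epsStep)
    }
    if (relChange(EHist) <= params$epsTol) { stopReason <- "tolerance"; break }
  }
  new("FPMReconstruction", object = iftc(s),
      pupil = new("FPMPupil", values = p, mask = mask, zernike = numeric()),
      history = data.frame(iteration = seq_len(k), Ep = EHist,
                           alphaStep = aHist, betaStep = bHist),
      iterations = k, stopReason = stopReason, solver = "gn",
      params = unclass(params))
}

#' Momentum-accelerated PIE reconstruction
#'
#' Sequential rPIE-style updates with heavy-ball momentum: each sweep
#' applies regularized quotient updates per illumination, and at the end of
#' the sweep a velocity term (decayed by `etaObj`/`etaPupil`, scaled by the
#' friction `gamma`) adds a further step along the sweep's displacement.
#' Pupil updates are suppressed until the global illumination-update
#' counter reaches `tPupil`; pupil momentum starts with the following
#' sweep. With `etaObj = etaPupil = 0` and `gamma = 0` the solver reduces
#' to plain sequential rPIE.
#'
#' @param ms an [FPMMeasurements-class].
#' @param pupil0 initial [FPMPupil-class].
#' @param params an [mpieParams()] list.
#' @return an [FPMReconstruction-class].
#' @export
fpmMPIE <- function(ms, pupil0 = makePupil(ms@config),
                    params = mpieParams()) {
  config <- ms@config
  ill <- ms@illuminations
  A <- measuredAmplitudes(ms)
  windows <- lapply(seq_len(nrow(ill)),
                    function(j) samplingWindow(ill[j, ], config))
  ord <- if (params$order == "na") naOrder(ill) else seq_len(nrow(ill))
  n <- config@hrSide
  s <- upsampledInit(A, ill, config)
  p <- pupil0@values; mask <- pupil0@mask
  vS <- matrix(0 + 0i, n, n); vP <- matrix(0 + 0i, nrow(p), ncol(p))
  aNorm <- sum(A^2)
  EHist <- numeric(); stopReason <- "maxIter"
  k <- 0L; updCount <- 0L; pupilActive <- FALSE
  while (k < params$maxIter) {
    k <- k + 1L
    sStart <- s; pStart <- p
    pupilWasActive <- pupilActive
    misfit <- 0
    for (j in ord) {
      updCount <- updCount + 1L
      st <- sweepStep(s, p, A[, , j], windows[[j]])
      misfit <- misfit + st$misfit
      pa2 <- Mod(p)^2
      sNew <- st$Sw + Conj(p) * st$dPsi /
        ((1 - params$alpha) * pa2 + params$alpha * max(pa2))
      if (updCount >= params$tPupil) {
        pupilActive <- TRUE
        sa2 <- Mod(st$Sw)^2
        sm <- sqrt(max(sa2))
        # normalized quotient step: the spectrum window spans many orders
        # of magnitude, so the pupil step is weighted per pixel rather than
        # by the global maximum alone
        p <- p + params$beta * sqrt(sa2) * Conj(st$Sw) * st$dPsi /
          (sm * (sa2 + 1e-10 * sm^2))
        p[!mask] <- 0 + 0i
      }
      win <- windows[[j]]
      s[win$rows, win$cols] <- sNew
    }
    # "bold" extra step along the accumulated velocity at the end of each
    # sweep; under heavy noise this is the documented source of the
    # method's late-iteration oscillation
    vS <- params$etaObj * vS + (s - sStart)
    s <- s + params$gamma * params$etaObj * vS
    if (pupilWasActive) {
      vP <- params$etaPupil * vP + (p - pStart)
      p <- p + params$gamma * params$etaPupil * vP
      p[!mask] <- 0 + 0i
    }
    EHist <- c(EHist, misfit / aNorm)
    checkDiverged(EHist[k], EHist[1], "mPIE", k)
    if (relChange(EHist) <= params$epsTol) { stopReason <- "tolerance"; break }
  }
  new("FPMReconstruction", object = iftc(s),
      pupil = new("FPMPupil", values = p, mask = mask, zernike = numeric()),
      history = data.frame(iteration = seq_len(k), Ep = EHist),
      iterations = k, stopReason = stopReason, solver = "mpie",
      params = unclass(params))
}
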