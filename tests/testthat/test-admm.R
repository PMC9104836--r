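# Subproblem-level checks of the scaled ADMM updates against the
# independent numeric oracles in helper-oracles.R, plus the solver-level
# contracts (initialization, stopping, determinism, error metrics).

test_that("updateQ matches a derivative-free minimizer of its subproblem", {
  for (seed in 1:4) {
    st <- randomAdmmState(n = 8, m = 4, nWin = 3, seed = seed)
    params <- admmParams(alpha = c(0.5, 1, 0.2, 2)[seed], betaScale = "raw")
    for (j in 1:3) {
      expect_lt(max(Mod(updateQ(st, params, j) - oracleQ(st, params, j))),
                1e-4)
    }
  }
})

test_that("updateS matches a dense normal-equations solve", {
  for (seed in 1:5) {
    st <- randomAdmmState(n = 8, m = 4, nWin = 3, seed = seed)
    params <- admmParams(alpha = 0.5, gamma = 0.3, betaScale = "raw")
    expect_lt(max(Mod(updateS(st, params) - oracleS(st, params))), 1e-8)
  }
})

test_that("updateP matches per-pixel scalar least squares", {
  for (seed in 1:5) {
    st <- randomAdmmState(n = 8, m = 4, nWin = 3, seed = seed)
    params <- admmParams(beta = 2.5, betaScale = "raw")
    expect_lt(max(Mod(updateP(st, params) - oracleP(st, params))), 1e-8)
  }
})

test_that("limit identities of the four updates", {
  st <- randomAdmmState(n = 8, m = 4, nWin = 3, seed = 9)

  # alpha -> infinity leaves q at its relaxation target
  pInf <- admmParams(alpha = Inf, betaScale = "raw")
  qt <- st$p * cropSpectrum(st$s, st$windows[[1]]) - st$w[, , 1]
  expect_equal(updateQ(st, pInf, 1), qt, tolerance = 1e-12)

  # alpha = 0 enforces the measured amplitudes exactly
  p0 <- admmParams(alpha = 0, betaScale = "raw")
  qNew <- updateQ(st, p0, 1)
  expect_equal(Mod(iftc(qNew)), st$A[, , 1], tolerance = 1e-10)

  # beta -> infinity drives the pupil to zero
  pB <- admmParams(beta = 1e14, betaScale = "raw")
  expect_lt(max(Mod(updateP(st, pB))), 1e-10)

  # gamma -> infinity anchors the spectrum at delta
  pG <- admmParams(gamma = Inf)
  expect_equal(updateS(st, pG), st$delta, tolerance = 1e-12)

  # eta = 0 freezes the multipliers; consistent state leaves them unchanged
  pE <- admmParams(eta = 0)
  expect_equal(updateOmega(st, pE, 1), st$w[, , 1], tolerance = 1e-14)
  stC <- st
  stC$q[, , 1] <- st$p * cropSpectrum(st$s, st$windows[[1]])
  expect_equal(updateOmega(stC, admmParams(), 1), stC$w[, , 1],
               tolerance = 1e-14)

  # single-step multiplier arithmetic: eta = 1, w = 0, q - p Q s = c
  stD <- st
  stD$w[, , 1] <- 0 + 0i
  cExp <- stD$q[, , 1] - stD$p * cropSpectrum(stD$s, stD$windows[[1]])
  expect_equal(updateOmega(stD, admmParams(eta = 1), 1), cExp,
               tolerance = 1e-14)
})

test_that("residuals and error metrics match direct summation", {
  st <- randomAdmmState(n = 8, m = 4, nWin = 2, seed = 3)
  # direct, loop-based evaluation
  RpRef <- 0
  for (j in 1:2) {
    e <- iftc(st$q[, , j])
    for (i in seq_len(16)) RpRef <- RpRef + (Mod(e[i]) - st$A[, , j][i])^2
  }
  qPrev <- st$q + (0.1 + 0.05i)
  RdRef <- sum(Mod(st$q - qPrev)^2)
  res <- admmResiduals(st, qPrev)
  expect_equal(res$Rp, RpRef, tolerance = 1e-12)
  expect_equal(res$Rd, RdRef, tolerance = 1e-12)
  expect_true(is.na(admmResiduals(st, NULL)$Rd))

  params <- admmParams(alpha = 0.5, eta = 2)
  em <- admmErrorMetrics(st, qPrev, params)
  expect_equal(em$Ep, RpRef / sum(st$A^2), tolerance = 1e-12)
  lam2 <- 0.5^2 * sum(Mod(st$w)^2)
  expect_equal(em$Ed, (0.5 / 2) * RdRef / lam2, tolerance = 1e-12)

  # amplitude-consistent q gives a zero primal metric
  stZ <- st
  for (j in 1:2) stZ$q[, , j] <- ftc(stZ$A[, , j] + 0i)
  expect_equal(admmErrorMetrics(stZ, NULL, params)$Ep, 0, tolerance = 1e-20)

  # Ep is invariant under joint rescaling of data and iterates
  stS <- st
  stS$A <- st$A * 2
  stS$q <- st$q * 2
  expect_equal(admmErrorMetrics(stS, NULL, params)$Ep,
               admmErrorMetrics(st, NULL, params)$Ep, tolerance = 1e-12)

  # zero multipliers give the dual-metric sentinel, not a crash
  stW <- st; stW$w[] <- 0 + 0i
  expect_true(is.na(admmErrorMetrics(stW, qPrev, params)$Ed))
})

test_that("initialization: flat object, zero multipliers, zero splitting gap", {
  cfg <- tinyConfig()
  ms <- simulateDataset(cfg, syntheticGroundTruth(cfg, seed = 2))
  st <- admmInitialize(ms, makePupil(cfg), admmParams())
  u0 <- iftc(st$s)
  expect_equal(Mod(u0), matrix(1, cfg@hrSide, cfg@hrSide), tolerance = 1e-10)
  expect_true(all(st$w == 0))
  # splitting-space primal residual vanishes by construction
  gap <- 0
  for (j in seq_along(st$windows))
    gap <- gap + sum(Mod(st$q[, , j] -
                           st$p * cropSpectrum(st$s, st$windows[[j]]))^2)
  expect_equal(gap, 0)
})

test_that("solver loop: zero-iteration run, stopping, determinism", {
  cfg <- tinyConfig()
  ms <- simulateDataset(cfg, syntheticGroundTruth(cfg, seed = 2))

  rec0 <- fpmADMM(ms, params = admmParams(maxIter = 0))
  expect_equal(rec0@iterations, 0)
  expect_equal(Mod(rec0@object), matrix(1, cfg@hrSide, cfg@hrSide),
               tolerance = 1e-10)

  # infinite tolerance: exactly one iteration
  rec1 <- fpmADMM(ms, params = admmParams(epsTol = Inf, maxIter = 50))
  expect_equal(rec1@iterations, 1)
  expect_identical(rec1@stopReason, "tolerance")

  # zero tolerance: runs to the cap
  rec2 <- fpmADMM(ms, params = admmParams(epsTol = 0, maxIter = 3))
  expect_equal(rec2@iterations, 3)
  expect_identical(rec2@stopReason, "maxIter")

  # determinism
  recA <- fpmADMM(ms, params = admmParams(maxIter = 4))
  recB <- fpmADMM(ms, params = admmParams(maxIter = 4))
  expect_identical(recA@object, recB@object)
  expect_identical(recA@history, recB@history)
})

test_that("noiseless self-consistency: truth is nearly a fixed point", {
  cfg <- smallConfig()
  truth <- syntheticGroundTruth(cfg, seed = 6)
  pupil <- makePupil(cfg)
  ms <- simulateDataset(cfg, truth, pupil)
  # gamma = 0: the pure-fidelity objective, whose fixed point is the truth
  params <- admmParams(gamma = 0)
  st <- admmInitialize(ms, pupil, params)
  # place the iterate at the ground truth on the solver's amplitude scale:
  # the simulator normalized intensities by the brightest mean, and the
  # solver rescales amplitudes by hr/lr; recover the consistent scale from
  # the centre-LED forward field
  uTrue <- complexObject(truth)
  S <- ftc(uTrue)
  centre <- which(ms@illuminations$shiftX == 0 & ms@illuminations$shiftY == 0)
  field <- iftc(pupil@values * cropSpectrum(S, st$windows[[centre]]))
  c0 <- sqrt(sum(st$A[, , centre]^2) / sum(Mod(field)^2))
  st$s <- S * c0
  for (j in seq_along(st$windows))
    st$q[, , j] <- st$p * cropSpectrum(st$s, st$windows[[j]])
  em0 <- admmErrorMetrics(st, NULL, params)
  expect_lt(em0$Ep, 1e-6)
  # one batch iteration moves the iterate only marginally
  sPrev <- st$s
  for (j in st$order) st$q[, , j] <- updateQ(st, params, j)
  st$s <- updateS(st, params)
  expect_lt(max(Mod(st$s - sPrev)) / max(Mod(sPrev)), 1e-3)
})

test_that("primal error decreases monotonically on noiseless data", {
  cfg <- smallConfig()
  truth <- syntheticGroundTruth(cfg, seed = 8)
  ms <- simulateDataset(cfg, truth, makePupil(cfg, zernike = c(0, 0, 0, 0.3)))
  rec <- fpmADMM(ms, params = admmParams(maxIter = 30, epsTol = 0))
  Ep <- rec@history$Ep[rec@history$iteration >= 5]
  # non-increasing after the first iterations, within 1% fluctuation
  expect_true(all(diff(Ep) <= 0.01 * Ep[-length(Ep)]))
  expect_lt(Ep[length(Ep)], Ep[1])
})

test_that("sequential schedule reproduces the batch fixed point shape", {
  cfg <- tinyConfig()
  truth <- syntheticGroundTruth(cfg, seed = 2)
  ms <- simulateDataset(cfg, truth)
  recSeq <- fpmADMM(ms, params = admmParams(maxIter = 5,
                                            schedule = "sequential"))
  recBat <- fpmADMM(ms, params = admmParams(maxIter = 5))
  expect_equal(dim(recSeq@object), dim(recBat@object))
  expect_equal(nrow(recSeq@history), nrow(recBat@history))
  # both reduce the primal error from the start
  expect_lt(tail(recSeq@history$Ep, 1), recSeq@history$Ep[1])
})
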