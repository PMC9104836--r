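test_that("self-adaptive step rule halves on error increase only", {
  expect_equal(adaptStep(c(0.5, 0.5), 1, 0.01), 1)        # flat: keep
  expect_equal(adaptStep(c(0.5, 0.4), 1, 0.01), 1)        # falling: keep
  expect_equal(adaptStep(c(0.4, 0.5), 1, 0.01), 0.5)      # rising 20%: halve
  expect_equal(adaptStep(c(0.5, 0.502), 2, 0.01), 2)      # rising 0.4%: keep
  expect_error(adaptStep(0.5, 1, 0.01))

  # hand-traced trajectory over a stated error sequence
  E <- c(1, 0.5, 0.55, 0.554, 0.3)
  a <- 1; trace <- a
  for (k in 2:5) { a <- adaptStep(E[1:k], a, 0.01); trace <- c(trace, a) }
  expect_equal(trace, c(1, 1, 0.5, 0.5, 0.5))
})

test_that("Gauss-Newton: step sizes never increase; degenerate halving", {
  cfg <- smallConfig()
  truth <- syntheticGroundTruth(cfg, seed = 11)
  ms <- simulateDataset(cfg, truth, makePupil(cfg, zernike = c(0, 0, 0, 0.4)))
  rec <- fpmGaussNewton(ms, params = gnParams(maxIter = 20, epsTol = 0))
  expect_true(all(diff(rec@history$alphaStep) <= 0))
  expect_true(all(diff(rec@history$betaStep) <= 0))

  # a rule that always fires halves the step every sweep: alpha0 / 2^k
  recH <- fpmGaussNewton(ms, params = gnParams(epsStep = -Inf, maxIter = 6,
                                               epsTol = 0))
  # the first sweep has no error history to adapt on; halving starts after
  expect_equal(recH@history$alphaStep, c(1, 1 / 2^(0:4)))
})

test_that("Gauss-Newton recovers object and pupil on noiseless data", {
  cfg <- smallConfig()
  truth <- syntheticGroundTruth(cfg, seed = 12)
  pupilTrue <- makePupil(cfg, zernike = c(0, 0, 0, 0.5, 0.3))
  ms <- simulateDataset(cfg, truth, pupilTrue)
  rec <- fpmGaussNewton(ms, params = gnParams(maxIter = 60, epsTol = 0))
  ev <- evaluateReconstruction(rec, truth)
  expect_gte(ev$amplitudeSSIM, 0.85)
  expect_gte(ev$phaseSSIM, 0.85)
  expect_gte(pupilPhaseCorrelation(rec@pupil, pupilTrue), 0.8)
})

test_that("mPIE: momentum degenerates to plain rPIE when switched off", {
  cfg <- tinyConfig()
  truth <- syntheticGroundTruth(cfg, seed = 13)
  ms <- simulateDataset(cfg, truth)
  # with etaObj = etaPupil = 0 the velocity never accumulates, so gamma
  # is irrelevant
  r1 <- fpmMPIE(ms, params = mpieParams(etaObj = 0, etaPupil = 0,
                                        gamma = 1, maxIter = 5, epsTol = 0))
  r2 <- fpmMPIE(ms, params = mpieParams(etaObj = 0, etaPupil = 0,
                                        gamma = 7, maxIter = 5, epsTol = 0))
  expect_identical(r1@object, r2@object)
})

test_that("mPIE: pupil updates are delayed until tPupil", {
  cfg <- tinyConfig()
  truth <- syntheticGroundTruth(cfg, seed = 13)
  ms <- simulateDataset(cfg, truth)
  p0 <- makePupil(cfg)
  # delay beyond the run length: pupil must come back untouched
  rec <- fpmMPIE(ms, p0, params = mpieParams(tPupil = 1e9, maxIter = 3,
                                             epsTol = 0))
  expect_identical(pupilValues(rec@pupil), pupilValues(p0))
  # default delay: pupil is modified
  rec2 <- fpmMPIE(ms, p0, params = mpieParams(maxIter = 3, epsTol = 0))
  expect_false(identical(pupilValues(rec2@pupil), pupilValues(p0)))
})

test_that("mPIE converges on noiseless data, faster with momentum", {
  cfg <- smallConfig()
  truth <- syntheticGroundTruth(cfg, seed = 14)
  pupilTrue <- makePupil(cfg, zernike = c(0, 0, 0, 0.5, 0.3))
  ms <- simulateDataset(cfg, truth, pupilTrue)
  recM <- fpmMPIE(ms, params = mpieParams(maxIter = 40, epsTol = 0))
  recP <- fpmMPIE(ms, params = mpieParams(etaObj = 0, etaPupil = 0,
                                          maxIter = 40, epsTol = 0))
  evM <- evaluateReconstruction(recM, truth)
  evP <- evaluateReconstruction(recP, truth)
  expect_gte(evM$amplitudeSSIM, 0.85)
  expect_gte(evM$phaseSSIM, 0.85)
  expect_gte(evP$amplitudeSSIM, 0.85)
  # momentum does not slow the error decay at matched iterations
  expect_lte(tail(recM@history$Ep, 1), 1.5 * tail(recP@history$Ep, 1))
})

test_that("all solvers share the dataset and bundle contracts", {
  cfg <- tinyConfig()
  truth <- syntheticGroundTruth(cfg, seed = 15)
  ms <- simulateDataset(cfg, truth)
  for (sv in c("admm", "gn", "mpie")) {
    rec <- reconstruct(ms, sv, maxIter = 2, epsTol = 0)
    expect_s4_class(rec, "FPMReconstruction")
    expect_identical(rec@solver, sv)
    expect_true(all(c("iteration", "Ep") %in% names(rec@history)))
    expect_equal(dim(rec@object), c(cfg@hrSide, cfg@hrSide))
    expect_equal(dim(pupilValues(rec@pupil)), c(cfg@lrSide, cfg@lrSide))
    # determinism
    rec2 <- reconstruct(ms, sv, maxIter = 2, epsTol = 0)
    expect_identical(rec@object, rec2@object)
  }
  expect_error(reconstruct(ms, "nope"))
})
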