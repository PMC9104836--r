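test_that("LED illumination geometry matches closed-form trigonometry", {
  cfg <- opticalConfig()   # 15 x 15, 4 mm pitch, 86 mm height
  ill <- ledIlluminations(cfg)
  expect_equal(nrow(ill), 225)

  centre <- ill[ill$row == 8 & ill$col == 8, ]
  expect_equal(centre$shiftX, 0)
  expect_equal(centre$shiftY, 0)
  expect_equal(centre$illumNA, 0)
  expect_equal(centre$regime, "brightfield")

  onePitch <- ill[ill$row == 8 & ill$col == 9, ]
  expect_equal(onePitch$illumNA, 4 / sqrt(4^2 + 86^2), tolerance = 1e-12)
  expect_lt(onePitch$illumNA, cfg@objectiveNA)
  expect_equal(onePitch$regime, "brightfield")
  # tilt frequency rounded onto the HR grid: 15 bins for one pitch
  expect_equal(onePitch$shiftX, 15)
  expect_equal(onePitch$shiftY, 0)

  corner <- ill[ill$row == 15 & ill$col == 15, ]
  r <- sqrt(2) * 28
  expect_equal(corner$illumNA, r / sqrt(r^2 + 86^2), tolerance = 1e-12)
  expect_gt(corner$illumNA, cfg@objectiveNA)
  expect_equal(corner$regime, "darkfield")

  # brightfield/darkfield split is exactly the <= objective-NA set
  expect_identical(ill$regime == "brightfield", ill$illumNA <= 0.1)
})

test_that("off-grid sampling windows are rejected, not wrapped", {
  # 4x magnification of the LED span pushes corner windows off the HR grid
  expect_error(suppressWarnings(ledIlluminations(opticalConfig(ledPitch = 16))),
               "off the HR grid")
})

test_that("samplingWindow errors on out-of-bounds shifts", {
  cfg <- tinyConfig()
  expect_error(samplingWindow(list(shiftX = 9, shiftY = 0), cfg),
               "outside the HR grid")
  win <- samplingWindow(list(shiftX = 0, shiftY = 0), cfg)
  # centred on the HR DC bin
  expect_true((cfg@hrSide / 2 + 1) %in% win$rows)
  expect_equal(win$rows[cfg@lrSide / 2 + 1], cfg@hrSide / 2 + 1)
})

test_that("crop and embed are exact adjoints on every window", {
  cfg <- tinyConfig()
  ill <- ledIlluminations(cfg)
  n <- cfg@hrSide
  set.seed(42)
  S <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  r <- matrix(complex(real = rnorm(cfg@lrSide^2),
                      imaginary = rnorm(cfg@lrSide^2)),
              cfg@lrSide, cfg@lrSide)
  for (j in seq_len(nrow(ill))) {
    win <- samplingWindow(ill[j, ], cfg)
    x <- cropSpectrum(S, win)
    # crop(embed(x)) is the identity on the window
    expect_identical(cropSpectrum(embedSpectrum(x, win, n), win), x)
    # <crop(S), r> == <S, embed(r)>
    lhs <- sum(Conj(x) * r)
    rhs <- sum(Conj(S) * embedSpectrum(r, win, n))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("pupil construction: aperture size, support and aberrations", {
  cfg <- opticalConfig()
  # closed-form radius: NA / (wavelength * frequency pitch) ~ 32.9 px
  expect_equal(pupilRadiusPx(cfg), 0.1 / (0.632 / (128 * 6.5 / 4)),
               tolerance = 1e-12)
  expect_equal(round(pupilRadiusPx(cfg)), 33)

  p <- makePupil(cfg)
  expect_true(all(Mod(pupilValues(p)[p@mask]) == 1))
  expect_true(all(pupilValues(p)[!p@mask] == 0))
  expect_true(all(Arg(pupilValues(p)[p@mask]) == 0))

  pAb <- makePupil(cfg, zernike = c(0, 0, 0, 0.5, 0.3))
  expect_true(all(abs(Mod(pupilValues(pAb)[pAb@mask]) - 1) < 1e-12))
  expect_true(any(Arg(pupilValues(pAb)[pAb@mask]) != 0))
  expect_identical(pAb@mask, p@mask)

  # aperture exceeding the grid is an error
  expect_error(makePupil(suppressWarnings(
    opticalConfig(objectiveNA = 0.5, ledPitch = 0.5,
                  lrSide = 16, hrSide = 32))),
               "exceeds")
})

test_that("Zernike defocus term reproduces its radial polynomial", {
  rho <- matrix(seq(0, 1, length.out = 5), 5, 5)
  theta <- matrix(0, 5, 5)
  z4 <- zernikePhase(c(0, 0, 0, 1), rho, theta)
  expect_equal(z4, sqrt(3) * (2 * rho^2 - 1), tolerance = 1e-12)
})

test_that("forward model: uniform object, Parseval, and direct-DFT oracle", {
  cfg <- tinyConfig()
  n <- cfg@hrSide
  pupil <- makePupil(cfg)
  win <- samplingWindow(list(shiftX = 0, shiftY = 0), cfg)

  flat <- new("FPMGroundTruth", amplitude = matrix(1, n, n),
              phase = matrix(0, n, n))
  I <- forwardIntensity(flat, pupil, win)
  expect_equal(max(I) - min(I), 0, tolerance = 1e-12 * max(I))

  set.seed(7)
  u <- matrix(runif(n^2, 0.2, 1), n, n) *
    exp(1i * matrix(runif(n^2, 0, 1), n, n))
  tr <- new("FPMGroundTruth", amplitude = Mod(u), phase = Arg(u))
  I2 <- forwardIntensity(tr, pupil, win)
  # Parseval: spatial intensity sum equals filtered spectral power
  S <- ftc(u)
  expect_equal(sum(I2),
               sum(Mod(pupilValues(pupil) * cropSpectrum(S, win))^2),
               tolerance = 1e-10)

  # FFT path vs brute-force DFT on every window of the tiny geometry
  ill <- ledIlluminations(cfg)
  for (j in c(1, 5, 9)) {
    winJ <- samplingWindow(ill[j, ], cfg)
    ref <- directDFTIntensity(u, pupilValues(pupil),
                              ill$shiftX[j], ill$shiftY[j])
    got <- forwardIntensity(tr, pupil, winJ)
    expect_lt(max(abs(got - ref)) / max(ref), 1e-10)
  }
})

test_that("simulateDataset is reproducible and correctly shaped", {
  cfg <- tinyConfig()
  truth <- syntheticGroundTruth(cfg, seed = 3)
  ms1 <- simulateDataset(cfg, truth,
                         noise = list(model = "gaussian", level = 0.5),
                         seed = 11)
  ms2 <- simulateDataset(cfg, truth,
                         noise = list(model = "gaussian", level = 0.5),
                         seed = 11)
  expect_identical(intensities(ms1), intensities(ms2))
  expect_equal(dim(intensities(ms1)), c(16, 16, 9))
  expect_true(all(intensities(ms1) >= 0))
  # brightest brightfield frame has mean one before noise
  clean <- simulateDataset(cfg, truth)
  bf <- which(illuminations(clean)$regime == "brightfield")
  expect_equal(max(apply(intensities(clean)[, , bf, drop = FALSE], 3, mean)),
               1, tolerance = 1e-12)
  expect_identical(noiseRecord(clean)$model, "none")
})

test_that("synthetic ground truth respects its declared ranges", {
  cfg <- tinyConfig()
  gt <- syntheticGroundTruth(cfg, seed = 5)
  expect_true(all(gt@amplitude >= 0.3 - 1e-12 & gt@amplitude <= 1 + 1e-12))
  expect_true(all(gt@phase >= 0 - 1e-12 & gt@phase <= pi / 2 + 1e-12))
  # seeded and reproducible, distinct fields
  gt2 <- syntheticGroundTruth(cfg, seed = 5)
  expect_identical(gt@amplitude, gt2@amplitude)
  expect_gt(stats::sd(gt@amplitude), 0)
  expect_false(isTRUE(all.equal(gt@amplitude / max(gt@amplitude),
                                gt@phase / max(gt@phase))))
})
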