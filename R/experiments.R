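# Experiment drivers: regenerate the simulation comparisons (noiseless
# convergence, Gaussian/Poisson noise-robustness sweeps) at a chosen scale.

solverTable <- function() {
  list(admm = function(ms, params) fpmADMM(ms, params = params),
       gn = function(ms, params) fpmGaussNewton(ms, params = params),
       mpie = function(ms, params) fpmMPIE(ms, params = params))
}

defaultSolverParams <- function(solver, maxIter, epsTol) {
  switch(solver,
    admm = admmParams(maxIter = maxIter, epsTol = epsTol),
    gn = gnParams(maxIter = maxIter, epsTol = epsTol),
    mpie = mpieParams(maxIter = maxIter, epsTol = epsTol),
    stop("unknown solver: ", solver))
}

#' Reconstruct one dataset with a named solver
#'
#' Thin dispatcher used by the comparison driver and the command-line
#' tools: `"admm"`, `"gn"` (sequential Gauss-Newton) or `"mpie"`.
#'
#' @param ms an [FPMMeasurements-class].
#' @param solver solver name.
#' @param params solver parameter list (defaults per solver).
#' @param maxIter,epsTol used when `params` is NULL.
#' @return an [FPMReconstruction-class].
#' @export
reconstruct <- function(ms, solver = c("admm", "gn", "mpie"),
                        params = NULL, maxIter = 100, epsTol = 1e-3) {
  solver <- match.arg(solver)
  if (is.null(params))
    params <- defaultSolverParams(solver, maxIter, epsTol)
  solverTable()[[solver]](ms, params)
}

#' Noise-robustness comparison sweep
#'
#' Runs every requested solver over a grid of noise conditions and seeds
#' on freshly simulated data (one ground truth and aberrated pupil per
#' seed), and tabulates SSIMs, iteration counts and stop reasons. With an
#' empty noise grid a single noiseless comparison per seed is run.
#'
#' @param config an [OpticalConfig-class]; the reduced
#'   [opticalConfigSmall()] profile keeps sweeps fast.
#' @param solvers character vector among `"admm"`, `"gn"`, `"mpie"`.
#' @param gaussianLevels numeric vector of Gaussian noise levels
#'   (fractions, e.g. 0.7 for 70%).
#' @param poissonSigmas numeric vector of Poisson sigma values.
#' @param seeds integer vector; each seed draws its own truth, pupil and
#'   noise realization.
#' @param zernike Zernike coefficients of the simulated pupil aberration.
#' @param maxIter,epsTol solver iteration cap and stopping tolerance.
#' @param outDir optional directory; when given, the report is written to
#'   `report.csv` and SSIM-vs-noise curves to `curves_<model>.png`.
#' @return data.frame with columns `solver`, `noiseModel`, `level`,
#'   `seed`, `amplitudeSSIM`, `phaseSSIM`, `iterations`, `stopReason`.
#' @export
runNoiseComparison <- function(config = opticalConfigSmall(),
                               solvers = c("admm", "gn", "mpie"),
                               gaussianLevels = numeric(),
                               poissonSigmas = numeric(),
                               seeds = 1:5,
                               zernike = c(0, 0, 0, 0.5, 0.3),
                               maxIter = 100, epsTol = 1e-3,
                               outDir = NULL) {
  stopifnot(length(solvers) >= 1, length(seeds) >= 1)
  grid <- rbind(
    if (length(gaussianLevels))
      data.frame(model = "gaussian", level = gaussianLevels),
    if (length(poissonSigmas))
      data.frame(model = "poisson", level = poissonSigmas))
  if (is.null(grid) || !nrow(grid)) grid <- data.frame(model = "none", level = 0)
  rows <- list()
  for (seed in seeds) {
    truth <- syntheticGroundTruth(config, seed = seed)
    pupilTrue <- makePupil(config, zernike = zernike)
    clean <- simulateDataset(config, truth, pupilTrue)
    for (g in seq_len(nrow(grid))) {
      ms <- switch(grid$model[g],
        none = clean,
        gaussian = addGaussianNoise(clean, level = grid$level[g],
                                    seed = seed + 1000L),
        poisson = addPoissonNoise(clean, sigma = grid$level[g],
                                  seed = seed + 1000L))
      for (sv in solvers) {
        rec <- reconstruct(ms, sv, maxIter = maxIter, epsTol = epsTol)
        ev <- evaluateReconstruction(rec, truth)
        rows[[length(rows) + 1L]] <- data.frame(
          solver = sv, noiseModel = grid$model[g], level = grid$level[g],
          seed = seed, amplitudeSSIM = ev$amplitudeSSIM,
          phaseSSIM = ev$phaseSSIM, iterations = rec@iterations,
          stopReason = rec@stopReason, stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(outDir, "report.csv"),
                     row.names = FALSE)
    writeManifest(outDir, config, solvers, grid, seeds, zernike,
                  maxIter, epsTol)
    for (model in setdiff(unique(report$noiseModel), "none"))
      plotNoiseCurves(report[report$noiseModel == model, ],
                      file.path(outDir, paste0("curves_", model, ".png")),
                      logX = model == "poisson")
  }
  report
}

writeManifest <- function(outDir, config, solvers, grid, seeds, zernike,
                          maxIter, epsTol) {
  jsonlite::write_json(
    list(format = "admmFPM-comparison", version = 1L,
         package_version = as.character(utils::packageVersion("admmFPM")),
         config = configToList(config), solvers = solvers,
         noise_grid = grid, seeds = seeds, zernike = zernike,
         max_iter = maxIter, eps_tol = epsTol),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}

# Median-over-seeds SSIM vs noise level, one line per solver.
plotNoiseCurves <- function(report, path, logX = FALSE) {
  agg <- stats::aggregate(cbind(amplitudeSSIM, phaseSSIM) ~ solver + level,
                          data = report, FUN = stats::median)
  grDevices::png(path, width = 1200, height = 500, res = 110)
  on.exit(grDevices::dev.off())
  oldPar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldPar), add = TRUE)
  for (what in c("amplitudeSSIM", "phaseSSIM")) {
    graphics::plot(NULL, xlim = range(agg$level), ylim = c(0, 1),
                   log = if (logX) "x" else "",
                   xlab = "noise level", ylab = what)
    solvers <- unique(agg$solver)
    for (i in seq_along(solvers)) {
      d <- agg[agg$solver == solvers[i], ]
      d <- d[order(d$level), ]
      graphics::lines(d$level, d[[what]], col = i, lwd = 2)
      graphics::points(d$level, d[[what]], col = i, pch = 16)
    }
    graphics::legend("bottomleft", legend = solvers, col = seq_along(solvers),
                     lwd = 2, bty = "n")
  }
  invisible(path)
}

#' Plot error-metric histories of several reconstructions
#'
#' Overlays the per-iteration normalized error metric of each
#' reconstruction (the primal metric for ADMM) on a log scale.
#'
#' @param recons named list of [FPMReconstruction-class] objects.
#' @param path optional PNG path; when NULL, plots to the active device.
#' @return invisibly, the data.frame of histories.
#' @export
plotErrorHistories <- function(recons, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500, res = 110)
    on.exit(grDevices::dev.off())
  }
  hs <- lapply(names(recons), function(nm) {
    h <- recons[[nm]]@history
    h <- h[h$iteration > 0, c("iteration", "Ep")]
    h$solver <- nm
    h
  })
  all <- do.call(rbind, hs)
  graphics::plot(NULL, xlim = range(all$iteration),
                 ylim = range(all$Ep[all$Ep > 0]), log = "y",
                 xlab = "iteration", ylab = "normalized error metric")
  for (i in seq_along(recons)) {
    h <- hs[[i]]
    graphics::lines(h$iteration, h$Ep, col = i, lwd = 2)
  }
  graphics::legend("topright", legend = names(recons),
                   col = seq_along(recons), lwd = 2, bty = "n")
  invisible(all)
}
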