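# Dataset container and reconstruction bundle I/O.
#
# A dataset directory holds: frames.tif (multi-frame 32-bit float TIFF,
# values scaled into [0, 1] with the scale factor in the metadata),
# geometry.yaml (all optical-configuration fields, the stack scale and the
# noise record), illuminations.csv (the per-LED table) and manifest.json
# (seeds/provenance). The container stores 32-bit floats; a write/read
# round trip reproduces the stored values exactly at that precision.

configToList <- function(config) {
  out <- lapply(slotNames(config), function(nm) slot(config, nm))
  names(out) <- slotNames(config)
  out
}

listToConfig <- function(lst) {
  do.call(opticalConfig, lst[c("wavelength", "magnification", "objectiveNA",
                               "sensorPixel", "ledRows", "ledCols",
                               "ledPitch", "ledHeight", "lrSide", "hrSide")])
}

writeScaledTIFF <- function(frames, path) {
  # frames: list of matrices; returns the offset/scale used
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  c(offset = lo, scale = scale)
}

readScaledTIFF <- function(path, offset, scale) {
  frames <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) f * scale + offset)
}

#' Read and write FPM dataset containers
#'
#' `writeDataset()` serializes an [FPMMeasurements-class] to a directory
#' (multi-frame float TIFF stack + YAML geometry/noise metadata + CSV LED
#' table + JSON manifest); `readDataset()` reconstructs it. The manifest
#' records the noise seed and parameter values so a container identifies
#' the exact conditions that produced it.
#'
#' @param ms an [FPMMeasurements-class].
#' @param dir directory path (created if missing).
#' @return `writeDataset()`: the directory, invisibly; `readDataset()`:
#'   an [FPMMeasurements-class].
#' @export
writeDataset <- function(ms, dir) {
  stopifnot(is(ms, "FPMMeasurements"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  I <- ms@intensities
  frames <- lapply(seq_len(dim(I)[3]), function(j) I[, , j])
  sc <- writeScaledTIFF(frames, file.path(dir, "frames.tif"))
  nr <- ms@noiseRecord
  yaml::write_yaml(list(
    config = configToList(ms@config),
    stack = list(frames = dim(I)[3], offset = as.numeric(sc["offset"]),
                 scale = as.numeric(sc["scale"])),
    noise_record = list(model = nr$model, level = nr$level,
                        threshold = nr$threshold,
                        seed = nr$seed, affected = as.integer(nr$affected))
  ), file.path(dir, "geometry.yaml"))
  utils::write.csv(ms@illuminations, file.path(dir, "illuminations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(format = "admmFPM-dataset", version = 1L,
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         noise_seed = nr$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "geometry.yaml"))
  config <- listToConfig(meta$config)
  frames <- readScaledTIFF(file.path(dir, "frames.tif"),
                           meta$stack$offset, meta$stack$scale)
  m <- config@lrSide
  I <- array(0, c(m, m, length(frames)))
  for (j in seq_along(frames)) I[, , j] <- frames[[j]]
  I[I < 0] <- 0   # float rounding guard
  ill <- utils::read.csv(file.path(dir, "illuminations.csv"),
                         stringsAsFactors = FALSE)
  nr <- meta$noise_record
  new("FPMMeasurements", intensities = I, illuminations = ill,
      config = config,
      noiseRecord = list(model = nr$model, level = nr$level,
                         threshold = nr$threshold, seed = nr$seed,
                         affected = as.integer(unlist(nr$affected))))
}

#' Write a reconstruction bundle
#'
#' Emits the standard comparison bundle: HR amplitude and phase images and
#' pupil amplitude/phase (32-bit float TIFFs with per-image offset/scale
#' recorded in images.yaml), plus the per-iteration error history as CSV.
#' All three solvers emit the identical format.
#'
#' @param recon an [FPMReconstruction-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeReconstruction <- function(recon, dir) {
  stopifnot(is(recon, "FPMReconstruction"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- list(amplitude = Mod(recon@object),
               phase = Arg(recon@object),
               pupil_amplitude = Mod(recon@pupil@values),
               pupil_phase = wrapPhase(Arg(recon@pupil@values)))
  ranges <- list()
  for (nm in names(imgs)) {
    sc <- writeScaledTIFF(imgs[nm], file.path(dir, paste0(nm, ".tif")))
    ranges[[nm]] <- list(offset = as.numeric(sc["offset"]),
                         scale = as.numeric(sc["scale"]))
  }
  yaml::write_yaml(list(solver = recon@solver,
                        iterations = recon@iterations,
                        stop_reason = recon@stopReason,
                        params = recon@params,
                        images = ranges),
                   file.path(dir, "images.yaml"))
  utils::write.csv(recon@history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}
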