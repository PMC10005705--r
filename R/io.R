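#' Read and write load-displacement curves as CSV
#'
#' Plain CSV with header columns `displacement_mm`, `load_n`.
#'
#' @param curve A load-displacement tibble.
#' @param path File path.
#' @return `read_curve()` returns the curve tibble; `write_curve()` returns
#'   `path` invisibly.
#' @export
write_curve <- function(curve, path) {
  curve <- as_curve(curve)
  utils::write.csv(curve[c("displacement_mm", "load_n")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  as_curve(utils::read.csv(path))
}

#' Read and write DMA traces as CSV
#'
#' Columns `time_s`, `stress_mpa`, `strain`; the drive frequency travels in
#' a `# frequency_hz=<value>` comment line at the top of the file.
#'
#' @param trace A DMA trace tibble with a `frequency_hz` attribute.
#' @param path File path.
#' @return `read_dma_trace()` returns the trace with its `frequency_hz`
#'   attribute restored; `write_dma_trace()` returns `path` invisibly.
#' @export
write_dma_trace <- function(trace, path) {
  trace <- validate_trace(trace)
  f <- attr(trace, "frequency_hz")
  if (is.null(f)) abort("trace has no `frequency_hz` attribute.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frequency_hz=%.10g", f), con)
  utils::write.csv(as.data.frame(trace)[c("time_s", "stress_mpa", "strain")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dma_trace
#' @export
read_dma_trace <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("frequency_hz=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) abort("missing `# frequency_hz=` header comment.")
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(out, "frequency_hz") <- as.numeric(m[2])
  class(out) <- c("dma_trace", class(out))
  out
}

#' Write and read a cohort table as tidy CSV
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  class(out) <- c("cohort_table", class(out))
  out
}

#' Write and read a voxel volume (NIfTI plus JSON sidecar)
#'
#' Volumes are stored as NIfTI (via RNifti, if installed) with the voxel
#' spacing in mm; the calibration state and, optionally, a calibration
#' curve travel in a JSON sidecar next to the image.
#'
#' @param volume A [voxel_volume()].
#' @param path Path ending in `.nii` or `.nii.gz`.
#' @param calibration Optional `calibration_curve` to record in the sidecar.
#' @return `read_volume()` returns the [voxel_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
write_volume <- function(volume, path, calibration = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing volumes requires the RNifti package.")
  }
  img <- RNifti::asNifti(volume$values,
                         pixdim = rep(volume$spacing, 3))
  RNifti::writeNifti(img, path)
  sidecar <- list(calibrated = volume$calibrated, spacing_mm = volume$spacing,
                  units = if (volume$calibrated) "mgHA/cm^3" else "attenuation_au")
  if (!is.null(calibration)) {
    sidecar$calibration <- list(slope = calibration$slope,
                                intercept = calibration$intercept,
                                r_squared = calibration$r_squared)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("reading volumes requires the RNifti package.")
  }
  img <- RNifti::readNifti(path)
  sidecar_path <- paste0(path, ".json")
  calibrated <- FALSE
  spacing <- RNifti::pixdim(img)[1]
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    calibrated <- isTRUE(sc$calibrated)
    if (!is.null(sc$spacing_mm)) spacing <- sc$spacing_mm
  }
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing, calibrated)
}

#' Write the full synthetic test corpus
#'
#' Generates and writes one specimen of every input the pipeline consumes -
#' a bending curve, a DMA trace per protocol frequency, a cohort table, and
#' phantom calibration readings - as plain-text fixtures under `dir`.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the files written.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study_config(seed = seed)
  g <- cfg$groups[1]
  files <- character()
  curve <- generate_bending_curve(cfg$mechanics[[g]]$truth, noise_sd = 0.05,
                                  seed = child_seed(seed, 1L))
  files <- c(files, write_curve(curve, file.path(dir, "bending_curve.csv")))
  proto <- cfg$options$dma_protocol
  for (f in proto$frequencies) {
    tr <- generate_dma_trace(cfg$viscoelastic[[g]], proto, f,
                             seed = child_seed(seed, 2L))
    p <- file.path(dir, sprintf("dma_trace_%gHz.csv", f))
    files <- c(files, write_dma_trace(tr, p))
  }
  coh <- generate_cohort(cfg$cohort, seed = child_seed(seed, 3L))
  files <- c(files, write_cohort(coh, file.path(dir, "cohort.csv")))
  ph <- generate_phantom_volume(cfg$phantoms[[g]], seed = child_seed(seed, 4L))
  utils::write.csv(ph$readings, file.path(dir, "phantom_readings.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(dir, "phantom_readings.csv"))
  invisible(files)
}
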