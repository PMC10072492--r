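# File formats: NIfTI volumes (with a JSON ground-truth sidecar for
# phantoms), CSV measurement series, CSV/JSON validation reports, YAML
# study configuration.

# our in-memory frame is LPS-like; NIfTI stores RAS
.lps2ras <- diag(c(-1, -1, 1, 1))

#' Write / read a volume as NIfTI
#'
#' Spacing, origin and direction are stored in the sform/qform; the package's
#' LPS-like axes are converted to the NIfTI RAS convention on disk.
#'
#' @param volume a [CTVolume-class].
#' @param path output .nii or .nii.gz path.
#' @return \code{writeVolume} returns \code{path} invisibly;
#'   \code{readVolume} returns a [CTVolume-class].
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  aff <- rbind(cbind(volume@direction %*% diag(volume@spacing),
                     volume@origin),
               c(0, 0, 0, 1))
  aff <- .lps2ras %*% aff
  img <- RNifti::asNifti(volume@values)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  aff <- .lps2ras %*% rbind(xf, c(0, 0, 0, 1))[1:4, ]
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  vals <- array(as.numeric(img), dim = dim(img))
  CTVolume(values = vals, spacing = spacing, origin = aff[1:3, 4],
           direction = M %*% diag(1 / spacing))
}

.specAsList <- function(spec) {
  nm <- slotNames(spec)
  out <- lapply(nm, function(s) {
    v <- slot(spec, s)
    if (is.matrix(v)) as.numeric(v) else v
  })
  names(out) <- nm
  out
}

#' Write / read a phantom with its ground-truth sidecar
#'
#' The volume goes to NIfTI; the ground-truth landmarks and the generating
#' spec go to \code{<path>.json}.
#'
#' @param volume a phantom [CTVolume-class] (from [buildPhantom()]).
#' @param path .nii.gz path; the sidecar is written next to it.
#' @export
writePhantom <- function(volume, path) {
  writeVolume(volume, path)
  side <- list(groundTruth = volume@meta$groundTruth)
  if (!is.null(volume@meta$spec))
    side$spec <- .specAsList(volume@meta$spec)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(path) {
  vol <- readVolume(path)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    vol@meta$groundTruth <- side$groundTruth
  }
  vol
}

#' Write / read a measurement series as CSV
#'
#' Columns: rater, replicate, set_angle_deg, measured_angle_deg and,
#' when present, measurement_order (the blinded randomised order).
#'
#' @param series a measurement series data frame.
#' @param path CSV path.
#' @export
writeMeasurementSeries <- function(series, path) {
  .checkSeries(series)
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurementSeries
#' @export
readMeasurementSeries <- function(path) {
  .checkSeries(read.csv(path))
}

#' Write a validation report as CSV tables plus JSON
#'
#' @param report a \code{neckValidationReport} (see
#'   [runValidationBattery()]).
#' @param dir output directory, created if needed.
#' @export
writeValidationReport <- function(report, dir) {
  stopifnot(inherits(report, "neckValidationReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(report$reliability, file.path(dir, "reliability.csv"),
            row.names = FALSE)
  write.csv(report$reliabilityPooled,
            file.path(dir, "reliability_pooled.csv"), row.names = FALSE)
  write.csv(report$pairedTests, file.path(dir, "paired_tests.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Study configuration
#'
#' @param levels set displacement levels, degrees.
#' @param replicates measurements per rater and level.
#' @param raters number of simulated raters.
#' @param seed integer master seed.
#' @param phantom,measure named lists of [PhantomSpec()] /
#'   [measureParams()] overrides.
#' @param hintCenterSd,hintAngleSd rater hint perturbation (mm, degrees).
#' @param outputDir output directory, "" for none.
#' @param saveVolumes also write each phantom as NIfTI.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(levels = c(-30, -20, -10, 10, 20, 30),
                      replicates = 10, raters = 2, seed = 1L,
                      phantom = list(), measure = list(),
                      hintCenterSd = 1.5, hintAngleSd = 2,
                      outputDir = "", saveVolumes = FALSE) {
  new("RunConfig", levels = as.numeric(levels),
      replicates = as.integer(replicates), raters = as.integer(raters),
      seed = as.integer(seed), phantom = phantom, measure = measure,
      hintCenterSd = hintCenterSd, hintAngleSd = hintAngleSd,
      outputDir = outputDir, saveVolumes = saveVolumes)
}

#' @param path YAML file with fields of [runConfig()].
#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}
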