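# Full in-silico validation study: phantom per level, blinded randomised
# measurement order per simulated rater, full pipeline per measurement,
# reliability battery on the resulting series.

# small random rotation applied to a unit direction (sd in degrees)
.perturbDirection <- function(dir, sdDeg) {
  d <- dir + rnorm(3) * tan(.deg2rad(sdDeg))
  d / sqrt(sum(d^2))
}

#' Run the goniometer validation study end to end
#'
#' For every displacement level and replicate a phantom is built with its
#' own noise seed; every simulated rater then measures it through the full
#' imaging pipeline with independently perturbed landmark hints, so
#' inter-rater differences arise through the geometry (alignment, contour,
#' fits) as they do for human investigators. Measurements are logged in a
#' blinded randomised order per rater, and the reliability battery is run
#' on the resulting series. Everything derives from the config seed.
#'
#' @param config a [RunConfig-class] (see [runConfig()]).
#' @return a list of class \code{neckStudy} with \code{series} (long-format
#'   data frame), \code{report} (validation battery), \code{log} (seeds and
#'   realised measurement order) and \code{config}.
#' @export
runStudy <- function(config) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  nL <- length(config@levels); nR <- config@replicates; nK <- config@raters

  res <- .withSeed(config@seed, {
    phantomSeeds <- matrix(sample.int(.Machine$integer.max - 1L, nL * nR),
                           nL, nR)
    rows <- vector("list", nL * nR * nK)
    ri <- 0L
    for (li in seq_len(nL)) {
      for (rp in seq_len(nR)) {
        spec <- do.call(PhantomSpec,
                        modifyList(list(setAngle = config@levels[li],
                                        seed = phantomSeeds[li, rp]),
                                   config@phantom))
        vol <- buildPhantom(spec)
        gt <- groundTruth(vol)
        params <- do.call(measureParams,
                          modifyList(list(side = spec@side), config@measure))
        if (config@saveVolumes && nzchar(config@outputDir)) {
          dir.create(file.path(config@outputDir, "volumes"),
                     showWarnings = FALSE, recursive = TRUE)
          writePhantom(vol, file.path(config@outputDir, "volumes",
                                      sprintf("phantom_L%+03d_r%02d.nii.gz",
                                              as.integer(config@levels[li]),
                                              rp)))
        }
        for (k in seq_len(nK)) {
          hintC <- gt$headCenter + rnorm(3) * config@hintCenterSd
          hintD <- .perturbDirection(gt$lateralNeckDirMedial,
                                     config@hintAngleSd)
          meas <- measureTorsion(vol, hintC, hintD, params)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(rater = k, replicate = rp,
                                   set_angle_deg = config@levels[li],
                                   measured_angle_deg = torsionAngle(meas),
                                   phantom_seed = phantomSeeds[li, rp])
        }
      }
    }
    series <- do.call(rbind, rows)
    # blinded randomised order per rater
    out <- lapply(seq_len(nK), function(k) {
      blk <- series[series$rater == k, ]
      blk <- blk[sample.int(nrow(blk)), ]
      blk$measurement_order <- seq_len(nrow(blk))
      blk
    })
    series <- do.call(rbind, out)
    rownames(series) <- NULL
    list(series = series, phantomSeeds = phantomSeeds)
  })

  report <- if (nR >= 2 && nK >= 2) runValidationBattery(res$series) else NULL
  log <- list(seed = config@seed,
              phantomSeeds = as.integer(res$phantomSeeds),
              levels = config@levels, replicates = nR, raters = nK,
              measurementOrder = split(res$series$measurement_order,
                                       res$series$rater),
              packageVersion =
                as.character(utils::packageVersion("neckangle")))
  study <- structure(list(series = res$series, report = report, log = log,
                          config = config), class = "neckStudy")
  if (nzchar(config@outputDir)) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    writeMeasurementSeries(res$series,
                           file.path(config@outputDir, "series.csv"))
    if (!is.null(report))
      writeValidationReport(report, file.path(config@outputDir, "report"))
    jsonlite::write_json(log, file.path(config@outputDir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.neckStudy <- function(x, ...) {
  agg <- aggregate(measured_angle_deg ~ set_angle_deg, x$series, mean)
  cat("Phantom validation study\n")
  cat(sprintf("  %d levels x %d replicates x %d raters\n",
              length(x$config@levels), x$config@replicates,
              x$config@raters))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  set %+6.1f deg -> mean measured %+7.2f deg\n",
                agg$set_angle_deg[i], agg$measured_angle_deg[i]))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
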