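# Debug overlay of the construction on the measured slab.

.drawCircle <- function(circle, col) {
  th <- seq(0, 2 * pi, length.out = 181)
  lines(circle@center[1] + circle@radius * cos(th),
        circle@center[2] + circle@radius * sin(th), col = col, lwd = 1.5)
  points(circle@center[1], circle@center[2], pch = 3, col = col)
}

.drawLine <- function(line, lim, col, lty = 1) {
  t <- c(-500, 500)
  lines(line@point[1] + t * line@direction[1],
        line@point[2] + t * line@direction[2], col = col, lty = lty)
}

#' Plot the measurement construction over the slab
#'
#' Renders the mean-projected slab with the tangent, parallel, the four
#' circles and both neck axes overlaid; useful for auditing a measurement
#' or for documentation figures.
#'
#' @param measurement a [TorsionMeasurement-class].
#' @param file optional PNG path; when NULL, plots to the active device.
#' @export
plotTorsionConstruction <- function(measurement, file = NULL) {
  stopifnot(is(measurement, "TorsionMeasurement"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  sl <- measurement@slice
  image(sl@s1, sl@s2, sl@values, col = grDevices::gray.colors(128),
        asp = 1, xlab = "neck axis, medial + (mm)",
        ylab = "ventral + (mm)",
        main = sprintf("direct torsion measurement: %+.2f deg",
                       measurement@angleDeg))
  lim <- range(sl@s1)
  .drawLine(measurement@tangent, lim, "orange")
  .drawLine(measurement@parallel, lim, "orange", lty = 2)
  cir <- measurement@circles
  .drawCircle(cir$head, "red")
  .drawCircle(cir$headOpening, "red")
  .drawCircle(cir$neck1, "cyan")
  .drawCircle(cir$neck2, "cyan")
  .drawLine(measurement@axes@medialAxis, lim, "red")
  .drawLine(measurement@axes@lateralAxis, lim, "cyan")
  invisible(measurement)
}
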