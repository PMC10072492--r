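#' Accessors
#'
#' Small accessor generics for the package classes: the voxel array, voxel
#' spacing and ground-truth metadata of a volume, the axes of a section
#' frame, the signed torsion angle and construction circles of a
#' measurement, and the ICC estimate.
#'
#' @param x an object of the documented class.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeArray", function(x) standardGeneric("volumeArray"))
#' @rdname accessors
#' @export
setMethod("volumeArray", "CTVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "CTVolume", function(x) x@meta$groundTruth)

#' @rdname accessors
#' @export
setGeneric("frameAxes", function(x) standardGeneric("frameAxes"))
#' @rdname accessors
#' @export
setMethod("frameAxes", "SectionFrame", function(x) x@axes)

#' @rdname accessors
#' @export
setGeneric("frameOrigin", function(x) standardGeneric("frameOrigin"))
#' @rdname accessors
#' @export
setMethod("frameOrigin", "SectionFrame", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("torsionAngle", function(x) standardGeneric("torsionAngle"))
#' @rdname accessors
#' @export
setMethod("torsionAngle", "TorsionMeasurement", function(x) x@angleDeg)

#' @rdname accessors
#' @export
setGeneric("constructionCircles",
           function(x) standardGeneric("constructionCircles"))
#' @rdname accessors
#' @export
setMethod("constructionCircles", "TorsionMeasurement", function(x) x@circles)

#' @rdname accessors
#' @export
setGeneric("iccEstimate", function(x) standardGeneric("iccEstimate"))
#' @rdname accessors
#' @export
setMethod("iccEstimate", "ICCResult", function(x) x@icc)

setMethod("show", "Circle2D", function(object) {
  cat(sprintf("Circle2D: center (%.3f, %.3f) mm, radius %.3f mm\n",
              object@center[1], object@center[2], object@radius))
})

setMethod("show", "Line2D", function(object) {
  cat(sprintf("Line2D: through (%.3f, %.3f), direction (%.4f, %.4f)\n",
              object@point[1], object@point[2],
              object@direction[1], object@direction[2]))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  gt <- object@meta$groundTruth
  if (!is.null(gt))
    cat(sprintf("  phantom ground truth: side %s, set angle %+.1f deg\n",
                gt$side, gt$setAngle))
})

setMethod("show", "SectionFrame", function(object) {
  cat("SectionFrame\n  origin:", sprintf("%.2f", object@origin), "mm\n")
  cat("  neck axis (medial):", sprintf("%.4f", object@axes[, 1]), "\n")
  cat("  section normal:    ", sprintf("%.4f", object@axes[, 3]), "\n")
})

setMethod("show", "Slice2D", function(object) {
  cat(sprintf("Slice2D: %d x %d px, %.2f mm in-plane, %.1f mm slab\n",
              nrow(object@values), ncol(object@values), object@spacing[1],
              object@slabThickness))
})

setMethod("show", "TorsionMeasurement", function(object) {
  cat(sprintf("TorsionMeasurement: %+.2f deg (anteversion positive)\n",
              object@angleDeg))
})

setMethod("show", "ICCResult", function(object) {
  if (object@degenerate) {
    cat("ICC (two-way mixed, absolute agreement, single measures): 1.00",
        "[exact agreement, zero error variance]\n")
  } else {
    cat(sprintf("ICC (%s): %.3f, 95%% CI %.3f-%.3f, p = %.3g\n",
                object@model, object@icc, object@ciLow, object@ciHigh,
                object@p))
  }
})

setMethod("show", "PairedTestResult", function(object) {
  cat(sprintf(
    "Paired t: mean diff %.2f (sd %.2f), 95%% CI (%.2f, %.2f), t = %.3f, df = %d, p = %.3f\n",
    object@meanDiff, object@sdDiff, object@ciLow, object@ciHigh, object@t,
    as.integer(object@df), object@p))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s femur, set angle %+.1f deg, head r %.1f mm, osteotomy at %.1f mm (gap %.1f mm)\n",
    object@side, object@setAngle, object@headRadius, object@osteotomyOffset,
    object@osteotomyGap))
})
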