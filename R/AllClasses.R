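#' @import methods
NULL

.unit_tol <- 1e-6

#' Circle in the reformatted section plane
#'
#' A circle primitive of the measurement construction, in physical (mm)
#' section coordinates: the best-fitting circle in the femoral head, the
#' circle at the lateral opening of the head, and the two circles inscribed
#' between the tangent and its parallel in the lateral neck.
#'
#' @slot center numeric(2), mm.
#' @slot radius positive length, mm.
#' @export
setClass("Circle2D", representation(center = "numeric", radius = "numeric"),
         validity = function(object) {
           if (length(object@center) != 2L || !all(is.finite(object@center)))
             return("center must be a finite numeric of length 2")
           if (length(object@radius) != 1L || !is.finite(object@radius) ||
               object@radius <= 0)
             return("radius must be a single positive number")
           TRUE
         })

#' @param center numeric(2) center, mm.
#' @param radius positive radius, mm.
#' @rdname Circle2D-class
#' @export
Circle2D <- function(center, radius)
  new("Circle2D", center = as.numeric(center), radius = as.numeric(radius))

#' Oriented line in the section plane
#'
#' Point plus unit direction; used for the supporting tangent along the
#' ventral cortex of the greater trochanter, its dorsal parallel, and the
#' two neck axes connecting circle centers.
#'
#' @slot point numeric(2), a point on the line, mm.
#' @slot direction numeric(2), unit direction.
#' @export
setClass("Line2D", representation(point = "numeric", direction = "numeric"),
         validity = function(object) {
           if (length(object@point) != 2L || !all(is.finite(object@point)))
             return("point must be a finite numeric of length 2")
           if (length(object@direction) != 2L ||
               abs(sqrt(sum(object@direction^2)) - 1) > .unit_tol)
             return("direction must be a unit 2-vector")
           TRUE
         })

#' @param point numeric(2), a point on the line.
#' @param direction numeric(2); normalised internally.
#' @rdname Line2D-class
#' @export
Line2D <- function(point, direction) {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < .unit_tol) stop("direction must be non-zero")
  new("Line2D", point = as.numeric(point), direction = direction / n)
}

#' Medial and lateral femoral neck axes
#'
#' @slot medialAxis [Line2D-class] through the centers of the head and
#'   head-opening circles (the medial fragment).
#' @slot lateralAxis [Line2D-class] through the centers of the two circles
#'   inscribed between tangent and parallel (the lateral fragment).
#' @export
setClass("AxisPair",
         representation(medialAxis = "Line2D", lateralAxis = "Line2D"),
         validity = function(object) {
           dm <- object@medialAxis@direction
           dl <- object@lateralAxis@direction
           cr <- dm[1] * dl[2] - dm[2] * dl[1]
           dp <- sum(dm * dl)
           pm <- object@medialAxis@point
           pl <- object@lateralAxis@point
           same_dir <- abs(cr) < 1e-12
           off <- (pm - pl) - sum((pm - pl) * dl) * dl
           if (same_dir && sqrt(sum(off^2)) < 1e-12 && abs(abs(dp) - 1) < 1e-12)
             return("medial and lateral axes must not be identical")
           TRUE
         })

#' @param medialAxis,lateralAxis [Line2D-class] objects.
#' @rdname AxisPair-class
#' @export
AxisPair <- function(medialAxis, lateralAxis)
  new("AxisPair", medialAxis = medialAxis, lateralAxis = lateralAxis)

#' A 3D scalar image volume
#'
#' Minimal volume container: voxel array plus the world-coordinate frame
#' (per-axis spacing in mm, world origin of voxel (1,1,1), and an orthonormal
#' direction matrix whose columns are the world directions of the voxel
#' axes). The package convention is a femur-centric LPS-like frame:
#' +x medial (for the default left side), +y ventral, +z superior.
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric(3), mm per voxel, strictly positive.
#' @slot origin numeric(3), world position of the first voxel, mm.
#' @slot direction 3 x 3 orthonormal matrix, columns are voxel axes in world.
#' @slot meta list; for phantoms this carries the ground-truth landmarks.
#' @export
setClass("CTVolume",
         representation(values = "array", spacing = "numeric",
                        origin = "numeric", direction = "matrix",
                        meta = "list"),
         prototype(meta = list()),
         validity = function(object) {
           if (length(dim(object@values)) != 3L)
             return("values must be a 3D array")
           if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
               any(object@spacing <= 0))
             return("spacing must be 3 strictly positive numbers")
           if (length(object@origin) != 3L || any(!is.finite(object@origin)))
             return("origin must be a finite numeric of length 3")
           D <- object@direction
           if (!all(dim(D) == c(3L, 3L)) ||
               max(abs(crossprod(D) - diag(3))) > 1e-6)
             return("direction must be a 3x3 orthonormal matrix")
           TRUE
         })

#' @param values,spacing,origin,direction,meta see slots.
#' @rdname CTVolume-class
#' @export
CTVolume <- function(values, spacing, origin = c(0, 0, 0),
                     direction = diag(3), meta = list())
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction, meta = meta)

#' Neck-aligned section frame
#'
#' Right-handed orthonormal frame centered on the femoral neck. Columns of
#' \code{axes} are: 1 the in-plane neck axis (pointing medially, toward the
#' head), 2 the in-plane normal (ventral for a left femur), 3 the section
#' normal. The axial section plane is spanned by columns 1 and 2.
#'
#' @slot origin world point, mm (head center shifted distally toward the
#'   calcar level).
#' @slot axes 3 x 3 orthonormal, right-handed.
#' @slot meta list with refinement results (refined head center, etc.).
#' @export
setClass("SectionFrame",
         representation(origin = "numeric", axes = "matrix", meta = "list"),
         prototype(meta = list()),
         validity = function(object) {
           if (length(object@origin) != 3L || any(!is.finite(object@origin)))
             return("origin must be finite numeric(3)")
           A <- object@axes
           if (!all(dim(A) == c(3L, 3L)) ||
               max(abs(crossprod(A) - diag(3))) > 1e-6)
             return("axes must be 3x3 orthonormal")
           if (det(A) < 0) return("axes must be right-handed")
           TRUE
         })

#' @param origin,axes,meta see slots.
#' @rdname SectionFrame-class
#' @export
SectionFrame <- function(origin, axes, meta = list())
  new("SectionFrame", origin = as.numeric(origin), axes = axes, meta = meta)

#' A resampled oblique section slab
#'
#' Mean-intensity projection of a slab of given thickness around the axial
#' plane of a [SectionFrame-class]. Pixel (i, j) sits at
#' \code{origin + s1[i] * axes[,1] + s2[j] * axes[,2]} in world coordinates.
#'
#' @slot values 2D numeric matrix (rows follow \code{s1}).
#' @slot s1,s2 in-plane physical coordinates of rows / columns, mm.
#' @slot spacing numeric(2), in-plane pixel spacing, mm.
#' @slot frame the generating [SectionFrame-class].
#' @slot slabThickness slab thickness, mm (> 0).
#' @export
setClass("Slice2D",
         representation(values = "matrix", s1 = "numeric", s2 = "numeric",
                        spacing = "numeric", frame = "SectionFrame",
                        slabThickness = "numeric"),
         validity = function(object) {
           if (nrow(object@values) != length(object@s1) ||
               ncol(object@values) != length(object@s2))
             return("values dimensions must match s1/s2 lengths")
           if (object@slabThickness <= 0)
             return("slabThickness must be positive")
           if (length(object@spacing) != 2L || any(object@spacing <= 0))
             return("spacing must be 2 positive numbers")
           TRUE
         })

#' Result of one direct torsion measurement
#'
#' Holds the signed angle (anteversion positive) and the full geometric
#' construction for audit: the four circles, the tangent and its parallel,
#' both axes, and provenance of the slab used.
#'
#' @slot angleDeg signed degrees, anteversion positive, |angle| <= 90.
#' @slot circles named list of four [Circle2D-class]: \code{head},
#'   \code{headOpening}, \code{neck1}, \code{neck2}.
#' @slot tangent,parallel [Line2D-class].
#' @slot axes [AxisPair-class].
#' @slot sliceRef list describing the slab (frame, thickness, spacing).
#' @slot slice the [Slice2D-class] the construction was drawn on.
#' @export
setClass("TorsionMeasurement",
         representation(angleDeg = "numeric", circles = "list",
                        tangent = "Line2D", parallel = "Line2D",
                        axes = "AxisPair", sliceRef = "list",
                        slice = "Slice2D"),
         validity = function(object) {
           if (length(object@angleDeg) != 1L || !is.finite(object@angleDeg) ||
               abs(object@angleDeg) > 90)
             return("angleDeg must be a single finite value with |angle| <= 90")
           need <- c("head", "headOpening", "neck1", "neck2")
           if (!all(need %in% names(object@circles)))
             return("circles must contain head, headOpening, neck1, neck2")
           TRUE
         })

#' Parametric proximal-femur phantom specification
#'
#' Describes the simplified parametric anatomy (sphere head, tapering
#' frustum neck, cylinder shaft, ellipsoid trochanters), the basicervical
#' osteotomy, and the goniometer setting: the medial (head) fragment is
#' rigidly rotated by \code{setAngle} about the displacement axis, a unit
#' vector through the osteotomy center, tilted by \code{axisTiltDeg} from
#' the shaft axis in the frontal plane. The default tilt equals
#' \code{neckShaftAngle - 90} so the axis is perpendicular to the native
#' neck axis and the dialed rotation equals the true inter-fragment version
#' change, which is how the angle jig is calibrated.
#'
#' All lengths in mm, angles in degrees, intensities in arbitrary CT-like
#' units.
#'
#' @slot headRadius femoral head radius.
#' @slot neckLength head center to neck base along the neck axis.
#' @slot neckRadiusMedial,neckRadiusLateral neck frustum radii at the head
#'   center and at the neck base (linear taper).
#' @slot shaftRadius proximal shaft radius.
#' @slot gtSemiaxes,ltSemiaxes greater / lesser trochanter ellipsoid
#'   semiaxes (world-axis aligned).
#' @slot gtVentralFacet the greater trochanter's anterior surface is cut
#'   flat at this ventral offset from the neck-axis plane, mm (the flattish
#'   anterior trochanteric cortex along which the tangent is drawn).
#' @slot nativeAnteversion baseline version of the intact neck, degrees.
#' @slot osteotomyOffset distance from head center to the osteotomy plane
#'   center along the neck axis (basicervical: proximal to both trochanters).
#' @slot osteotomyGap separation held between the cut faces by the jig; must
#'   be wide enough that a +/-30 degree swing does not collide.
#' @slot setAngle dialed displacement, degrees, anteversion positive,
#'   within [-30, 30].
#' @slot neckShaftAngle angle between neck and shaft axes, degrees.
#' @slot axisTiltDeg frontal-plane tilt of the displacement axis from the
#'   shaft axis; NA means \code{neckShaftAngle - 90}.
#' @slot voxelSpacing numeric(3), mm.
#' @slot corticalValue,trabecularValue,backgroundValue intensities.
#' @slot shellThickness cortical shell thickness, mm.
#' @slot noiseSd additive Gaussian noise sd, intensity units.
#' @slot seed integer RNG seed for the noise.
#' @slot side "left" (default) or "right" (mirrored geometry).
#' @slot extent 3 x 2 matrix of world extents (min, max per axis), mm.
#' @export
setClass("PhantomSpec",
         representation(headRadius = "numeric", neckLength = "numeric",
                        neckRadiusMedial = "numeric",
                        neckRadiusLateral = "numeric", shaftRadius = "numeric",
                        gtSemiaxes = "numeric", ltSemiaxes = "numeric",
                        gtVentralFacet = "numeric",
                        nativeAnteversion = "numeric",
                        osteotomyOffset = "numeric", osteotomyGap = "numeric",
                        setAngle = "numeric", neckShaftAngle = "numeric",
                        axisTiltDeg = "numeric", voxelSpacing = "numeric",
                        corticalValue = "numeric", trabecularValue = "numeric",
                        backgroundValue = "numeric", shellThickness = "numeric",
                        noiseSd = "numeric", seed = "integer",
                        side = "character", extent = "matrix"),
         validity = function(object) {
           if (abs(object@setAngle) > 30)
             return("setAngle must lie within [-30, 30] degrees")
           if (any(object@voxelSpacing <= 0))
             return("voxelSpacing must be strictly positive")
           if (!(object@headRadius > object@neckRadiusMedial &&
                 object@neckRadiusMedial > 0))
             return("need headRadius > neckRadiusMedial > 0")
           if (object@osteotomyOffset - object@osteotomyGap / 2 <=
               object@headRadius * 0.8)
             return("osteotomy must leave a medial neck stump distal to the head")
           if (object@osteotomyOffset + object@osteotomyGap / 2 >=
               object@neckLength)
             return(paste("osteotomy must be basicervical: proximal to the",
                          "intertrochanteric region (both trochanters on the",
                          "lateral fragment)"))
           if (object@noiseSd < 0) return("noiseSd must be non-negative")
           if (object@gtVentralFacet >= object@gtSemiaxes[2])
             return("gtVentralFacet must cut the trochanter ellipsoid")
           if (!object@side %in% c("left", "right"))
             return("side must be 'left' or 'right'")
           if (!all(dim(object@extent) == c(3L, 2L)) ||
               any(object@extent[, 2] <= object@extent[, 1]))
             return("extent must be a 3x2 matrix of increasing bounds")
           TRUE
         })

#' Intraclass correlation result
#'
#' Single-measures, absolute-agreement ICC from the two-way model, ICC(A,1),
#' with the F-based 95 percent confidence interval and p-value.
#'
#' @slot icc estimate in [-1, 1].
#' @slot ciLow,ciHigh confidence bounds.
#' @slot p p-value for the test of ICC = 0.
#' @slot model label of the ICC flavor.
#' @slot nSubjects,kRaters design counts.
#' @slot degenerate TRUE when between-measurement variance is exactly zero
#'   (exact agreement reported instead of an undefined F ratio).
#' @export
setClass("ICCResult",
         representation(icc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        p = "numeric", model = "character",
                        nSubjects = "integer", kRaters = "integer",
                        degenerate = "logical"),
         validity = function(object) {
           if (!object@degenerate) {
             if (object@ciLow > object@icc + 1e-9 ||
                 object@ciHigh < object@icc - 1e-9)
               return("confidence interval must bracket the estimate")
             if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
           }
           TRUE
         })

#' Paired t-test result
#'
#' @slot meanDiff,sdDiff mean and sd of the paired differences, degrees.
#' @slot ciLow,ciHigh confidence bounds for the mean difference.
#' @slot t,df,p test statistic, degrees of freedom, two-tailed p.
#' @export
setClass("PairedTestResult",
         representation(meanDiff = "numeric", sdDiff = "numeric",
                        ciLow = "numeric", ciHigh = "numeric", t = "numeric",
                        df = "numeric", p = "numeric"),
         validity = function(object) {
           if (object@ciLow > object@meanDiff + 1e-9 ||
               object@ciHigh < object@meanDiff - 1e-9)
             return("confidence interval must bracket the mean difference")
           if (object@df != round(object@df) || object@df < 1)
             return("df must be a positive integer (n - 1)")
           TRUE
         })

#' Configuration of a full phantom validation study
#'
#' @slot levels set displacement levels, degrees.
#' @slot replicates measurements per rater and level.
#' @slot raters number of simulated raters.
#' @slot seed integer master seed; all randomness derives from it.
#' @slot phantom named list of [PhantomSpec()] overrides.
#' @slot measure named list of [measureParams()] overrides.
#' @slot hintCenterSd sd of the head-center hint perturbation, mm.
#' @slot hintAngleSd sd of the neck-direction hint perturbation, degrees.
#' @slot outputDir optional output directory ("" for none).
#' @slot saveVolumes write phantom volumes as NIfTI when outputDir is set.
#' @export
setClass("RunConfig",
         representation(levels = "numeric", replicates = "integer",
                        raters = "integer", seed = "integer",
                        phantom = "list", measure = "list",
                        hintCenterSd = "numeric", hintAngleSd = "numeric",
                        outputDir = "character", saveVolumes = "logical"),
         validity = function(object) {
           if (length(object@levels) == 0) return("levels must be non-empty")
           if (object@replicates < 1) return("replicates must be >= 1")
           if (object@raters < 1) return("raters must be >= 1")
           if (length(object@seed) != 1L || is.na(object@seed))
             return("seed must be set explicitly for reproducibility")
           TRUE
         })
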