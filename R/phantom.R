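# Parametric proximal-femur voxel phantom with a basicervical osteotomy and
# a goniometer-controlled medial-fragment rotation.

.deg2rad <- function(x) x * pi / 180

# Rodrigues rotation matrix about unit axis a by angle deg
.rotationMatrix <- function(a, deg) {
  th <- .deg2rad(deg)
  a <- a / sqrt(sum(a^2))
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# evaluate expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a phantom specification
#'
#' Defaults describe an adult-sized left femur at a clinical CT resolution:
#' 24 mm head radius, 50 mm neck with a 13 to 16 mm tapering radius, a
#' basicervical osteotomy 32 mm from the head center, and 0.6 x 0.6 x 1.0 mm
#' voxels with background 0, trabecular 300 and cortical 1200 intensity.
#' The jig holds the fragments 10 mm apart so that the full +/-30 degree
#' swing stays collision-free. See [PhantomSpec-class] for slot meanings.
#'
#' @param headRadius,neckLength,neckRadiusMedial,neckRadiusLateral,shaftRadius
#'   lengths, mm.
#' @param gtSemiaxes,ltSemiaxes trochanter ellipsoid semiaxes, mm.
#' @param gtVentralFacet flat anterior trochanteric facet offset, mm.
#' @param nativeAnteversion,setAngle,neckShaftAngle,axisTiltDeg degrees;
#'   \code{axisTiltDeg = NA} tilts the displacement axis perpendicular to
#'   the native neck axis.
#' @param osteotomyOffset,osteotomyGap,shellThickness lengths, mm.
#' @param voxelSpacing numeric(3), mm.
#' @param corticalValue,trabecularValue,backgroundValue,noiseSd intensities.
#' @param seed integer seed for the additive noise.
#' @param side "left" or "right".
#' @param extent optional 3 x 2 world bounds, mm.
#' @return a [PhantomSpec-class].
#' @export
PhantomSpec <- function(setAngle = 0, headRadius = 24, neckLength = 50,
                        neckRadiusMedial = 13, neckRadiusLateral = 16,
                        shaftRadius = 16, gtSemiaxes = c(14, 24, 30),
                        ltSemiaxes = c(12, 11, 16), gtVentralFacet = 20,
                        nativeAnteversion = 0,
                        osteotomyOffset = 32, osteotomyGap = 10,
                        neckShaftAngle = 130, axisTiltDeg = NA_real_,
                        voxelSpacing = c(0.6, 0.6, 1.0),
                        corticalValue = 1200, trabecularValue = 300,
                        backgroundValue = 0, shellThickness = 1.5,
                        noiseSd = 20, seed = 1L,
                        side = c("left", "right"), extent = NULL) {
  side <- match.arg(side)
  if (is.na(axisTiltDeg)) axisTiltDeg <- neckShaftAngle - 90
  if (is.null(extent)) {
    extent <- matrix(c(-52, 50, -44, 44, -62, 46), 3, 2, byrow = TRUE)
    if (side == "right") extent[1, ] <- c(-50, 52)
  }
  new("PhantomSpec", headRadius = headRadius, neckLength = neckLength,
      neckRadiusMedial = neckRadiusMedial,
      neckRadiusLateral = neckRadiusLateral, shaftRadius = shaftRadius,
      gtSemiaxes = as.numeric(gtSemiaxes), ltSemiaxes = as.numeric(ltSemiaxes),
      gtVentralFacet = gtVentralFacet,
      nativeAnteversion = nativeAnteversion,
      osteotomyOffset = osteotomyOffset, osteotomyGap = osteotomyGap,
      setAngle = setAngle, neckShaftAngle = neckShaftAngle,
      axisTiltDeg = axisTiltDeg, voxelSpacing = as.numeric(voxelSpacing),
      corticalValue = corticalValue, trabecularValue = trabecularValue,
      backgroundValue = backgroundValue, shellThickness = shellThickness,
      noiseSd = noiseSd, seed = as.integer(seed), side = side,
      extent = extent)
}

# Landmarks of the phantom in world coordinates (mm). Canonical frame:
# +x medial, +y ventral, +z superior; origin at the osteotomy-plane center.
# side == "right" mirrors x, and the dialed rotation is applied with the
# opposite handedness so that positive setAngle is anteversion (head moving
# ventrally) on both sides.
.phantomGeometry <- function(spec) {
  eps <- .deg2rad(spec@neckShaftAngle - 90)
  a0 <- .deg2rad(spec@nativeAnteversion)
  d <- c(cos(eps) * cos(a0), cos(eps) * sin(a0), sin(eps))   # medial-ward
  tilt <- .deg2rad(spec@axisTiltDeg)
  axis <- c(-sin(tilt), 0, cos(tilt))   # frontal-plane tilt from the shaft
  mirror <- if (spec@side == "right") c(-1, 1, 1) else c(1, 1, 1)
  d <- d * mirror
  axis <- axis * mirror
  O <- c(0, 0, 0)
  H0 <- O + spec@osteotomyOffset * d
  B <- H0 - spec@neckLength * d
  gtCenter <- B - 20 * d
  ltCenter <- B + c(6 * mirror[1], -22, -14)
  thetaEff <- if (spec@side == "left") spec@setAngle else -spec@setAngle
  R <- .rotationMatrix(axis, thetaEff)
  list(d = d, axis = axis, O = O, H0 = H0, B = B,
       gtCenter = gtCenter, ltCenter = ltCenter,
       shaftXY = B[1:2], shaftZ = c(B[3] - 55, B[3] + 4),
       thetaEff = thetaEff, R = R,
       headCenter = as.numeric(R %*% H0),
       neckDirMedial = as.numeric(R %*% d))
}

#' Build the goniometer phantom volume
#'
#' Voxelises the two fragments: the lateral fragment (shaft, both
#' trochanters, lateral neck stump) stays fixed; the medial fragment
#' (femoral head plus medial neck stump) is rigidly rotated by the set
#' angle about the displacement axis through the osteotomy center. Each
#' shape carries a cortical shell over a trabecular interior; Gaussian
#' noise is added with the spec's seed. Ground-truth landmarks (head
#' center, fragment neck axes, osteotomy center, displacement axis) are
#' attached to the volume metadata.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [CTVolume-class] with \code{groundTruth()} metadata.
#' @examples
#' vol <- buildPhantom(PhantomSpec(setAngle = 10, voxelSpacing = rep(2, 3)))
#' groundTruth(vol)$setAngle
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  g <- .phantomGeometry(spec)
  sp <- spec@voxelSpacing
  xs <- seq(spec@extent[1, 1], spec@extent[1, 2], by = sp[1])
  ys <- seq(spec@extent[2, 1], spec@extent[2, 2], by = sp[2])
  zs <- seq(spec@extent[3, 1], spec@extent[3, 2], by = sp[3])
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)

  sphere <- function(x, y, z, c0, r) {
    (x - c0[1])^2 + (y - c0[2])^2 + (z - c0[3])^2 <= r^2
  }
  ellipsoid <- function(x, y, z, c0, ax) {
    ((x - c0[1]) / ax[1])^2 + ((y - c0[2]) / ax[2])^2 +
      ((z - c0[3]) / ax[3])^2 <= 1
  }
  # neck frustum: s measured from the head center along -d (lateral-ward),
  # radius tapering linearly from neckRadiusMedial (s = 0) to
  # neckRadiusLateral (s = neckLength)
  frustum <- function(x, y, z, sRange, shrink) {
    dx <- x - g$H0[1]; dy <- y - g$H0[2]; dz <- z - g$H0[3]
    s <- -(dx * g$d[1] + dy * g$d[2] + dz * g$d[3])
    rad2 <- dx^2 + dy^2 + dz^2 - s^2
    r <- spec@neckRadiusMedial +
      (spec@neckRadiusLateral - spec@neckRadiusMedial) * s / spec@neckLength
    r <- pmax(r - shrink, 0)
    s >= sRange[1] & s <= sRange[2] & rad2 <= r^2
  }
  cylinderShaft <- function(x, y, z, shrink) {
    zr <- g$shaftZ + c(shrink, -shrink)
    (x - g$shaftXY[1])^2 + (y - g$shaftXY[2])^2 <=
      max(spec@shaftRadius - shrink, 0)^2 & z >= zr[1] & z <= zr[2]
  }

  half <- spec@osteotomyGap / 2
  medial <- function(x, y, z, shrink) {
    sphere(x, y, z, g$H0, spec@headRadius - shrink) |
      frustum(x, y, z, c(0, spec@osteotomyOffset - half - shrink), shrink)
  }
  lateral <- function(x, y, z, shrink) {
    frustum(x, y, z,
            c(spec@osteotomyOffset + half + shrink, spec@neckLength + 6),
            shrink) |
      cylinderShaft(x, y, z, shrink) |
      (ellipsoid(x, y, z, g$gtCenter, pmax(spec@gtSemiaxes - shrink, 0.1)) &
         y <= g$gtCenter[2] + spec@gtVentralFacet - shrink) |
      ellipsoid(x, y, z, g$ltCenter, pmax(spec@ltSemiaxes - shrink, 0.1))
  }

  # medial fragment is tested in the unrotated pose via inverse rotation
  Rt <- t(g$R)
  qx <- Rt[1, 1] * px + Rt[1, 2] * py + Rt[1, 3] * pz
  qy <- Rt[2, 1] * px + Rt[2, 2] * py + Rt[2, 3] * pz
  qz <- Rt[3, 1] * px + Rt[3, 2] * py + Rt[3, 3] * pz

  medFull <- medial(qx, qy, qz, 0)
  latFull <- lateral(px, py, pz, 0)
  overlap <- sum(medFull & latFull)
  if (overlap > max(10, 0.002 * sum(medFull)))
    stop(sprintf(paste("fragments collide at set angle %+0.1f deg (%d voxels",
                       "overlap): physically impossible configuration"),
                 spec@setAngle, overlap))
  sh <- spec@shellThickness
  core <- medial(qx, qy, qz, sh) | lateral(px, py, pz, sh)

  vals <- rep(spec@backgroundValue, nx * ny * nz)
  vals[medFull | latFull] <- spec@corticalValue
  vals[core] <- spec@trabecularValue
  if (spec@noiseSd > 0)
    vals <- vals + .withSeed(spec@seed,
                             rnorm(length(vals), sd = spec@noiseSd))
  dim(vals) <- c(nx, ny, nz)

  gt <- list(setAngle = spec@setAngle, side = spec@side,
             headCenter = g$headCenter, neckDirMedial = g$neckDirMedial,
             lateralNeckDirMedial = g$d, osteotomyCenter = g$O,
             displacementAxis = g$axis, headRadius = spec@headRadius,
             osteotomyOffset = spec@osteotomyOffset,
             neckLength = spec@neckLength, seed = spec@seed)
  CTVolume(values = vals, spacing = sp,
           origin = spec@extent[, 1], direction = diag(3),
           meta = list(groundTruth = gt, spec = spec))
}

#' Simulate a goniometer measurement series without imaging
#'
#' Fast statistical stand-in for the full imaging pipeline: each measured
#' angle is the set level plus a rater-specific systematic bias plus
#' Gaussian rater noise. Rows are shuffled within each rater to emulate the
#' blinded, randomised measurement order; the realised order is kept in the
#' \code{measurement_order} column. Fully reproducible from the seed.
#'
#' @param levels set displacement levels, degrees.
#' @param replicates measurements per rater and level (>= 2).
#' @param raters number of raters (>= 2).
#' @param raterBias numeric, systematic offset per rater, degrees.
#' @param raterNoiseSd measurement noise sd, degrees (>= 0).
#' @param seed integer.
#' @return a long-format \code{data.frame} with columns \code{rater},
#'   \code{replicate}, \code{set_angle_deg}, \code{measured_angle_deg},
#'   \code{measurement_order}.
#' @export
simulateGoniometerSeries <- function(levels = c(-30, -20, -10, 10, 20, 30),
                                     replicates = 10, raters = 2,
                                     raterBias = rep(0, raters),
                                     raterNoiseSd = 1.5, seed = 1L) {
  if (replicates < 2) stop("replicates must be >= 2")
  if (raters < 2) stop("raters must be >= 2")
  if (raterNoiseSd < 0) stop("raterNoiseSd must be non-negative")
  if (length(raterBias) == 1L) raterBias <- rep(raterBias, raters)
  if (length(raterBias) != raters)
    stop("raterBias must have one entry per rater")
  .withSeed(seed, {
    out <- lapply(seq_len(raters), function(r) {
      df <- expand.grid(replicate = seq_len(replicates),
                        set_angle_deg = levels)
      df$rater <- r
      df$measured_angle_deg <- df$set_angle_deg + raterBias[r] +
        rnorm(nrow(df), sd = raterNoiseSd)
      ord <- sample.int(nrow(df))
      df <- df[ord, ]
      df$measurement_order <- seq_len(nrow(df))
      df
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[, c("rater", "replicate", "set_angle_deg", "measured_angle_deg",
            "measurement_order")]
  })
}
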