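# End-to-end direct measurement: neck-aligned reformat, 5 mm axial slab,
# cortex contours, tangent/parallel band, circle fits, intersection angle.

#' Measurement-pipeline parameters
#'
#' Tunable parameters of the direct measurement, all in mm or degrees.
#' Windows are expressed along the in-plane neck axis relative to the
#' refined head center (negative = lateral): \code{gtWindow} selects the
#' greater-trochanter region for the ventral tangent, \code{ltWindow} the
#' lesser-trochanter/dorsal-neck region for the parallel. \code{stations}
#' are the fractions of the band extent (from the lateral head opening
#' toward the lateral cortex) at which the two neck circles are inscribed;
#' the operator chooses these freely in the planning software, the defaults
#' place them in the middle half of the band. \code{headArcBand} and
#' \code{openingBand} select medial-fragment boundary points by their
#' distance from the head center in units of the estimated head-disk
#' radius: points near the disk radius form the head arc, points beyond it
#' belong to the neck stump silhouette at the lateral opening of the head.
#'
#' @param boneThreshold intensity separating bone from background.
#' @param slabThickness axial slab thickness, mm.
#' @param inPlaneExtent section extents \code{c(s1min, s1max, s2min, s2max)}
#'   relative to the frame origin, mm.
#' @param headRadiusEst approximate femoral head radius, mm.
#' @param headBallFactor the head center is refined as the bone centroid in
#'   a ball of \code{headBallFactor * headRadiusEst}.
#' @param centerIterations recentering iterations for the head centroid.
#' @param corticalThreshold intensity above which voxels are treated as
#'   cortical shell for the final sphere fit of the head center.
#' @param lateralExclusionRadius bone farther than this from the refined
#'   head center is treated as the lateral fragment when refining the neck
#'   direction, mm (large enough to cover head plus medial stump).
#' @param anchorDepth depth of the osteotomy-face anchor window measured
#'   from the medial tip of the lateral fragment, mm.
#' @param corridorRange,corridorRadius lateral corridor used to refine the
#'   neck direction: along-axis range (relative to the lateral fragment's
#'   medial tip) and maximal distance from the evolving axis, mm.
#' @param calcarOffsetMm distal shift of the frame origin along the scanner
#'   axis, guiding the section down toward the calcar (Adam's bow).
#' @param gtWindow,ltWindow landmark windows, mm (see above).
#' @param stations two fractions in (0, 1).
#' @param headArcBand,openingBand radial bands in units of the estimated
#'   head-disk radius.
#' @param facetDepth the tangent direction is refined on the subpixel
#'   ventral cortex profile within this depth of the supporting point, mm.
#' @param side "left" or "right"; fixes the ventral direction and thereby
#'   the anteversion-positive sign convention.
#' @param slabSpacing in-plane pixel spacing; default = finest voxel
#'   spacing.
#' @param fill intensity assigned to slab samples outside the volume.
#' @return a named list of parameters.
#' @export
measureParams <- function(boneThreshold = 150, slabThickness = 5,
                          inPlaneExtent = c(-100, 40, -48, 48),
                          headRadiusEst = 24, headBallFactor = 1.1,
                          centerIterations = 3, corticalThreshold = 750,
                          lateralExclusionRadius = 34, anchorDepth = 4,
                          corridorRange = c(6, 40), corridorRadius = 12,
                          calcarOffsetMm = 10,
                          gtWindow = c(-90, -50), ltWindow = c(-68, -40),
                          stations = c(0.35, 0.65),
                          headArcBand = c(0.85, 1.02),
                          openingBand = c(1.05, 1.45), facetDepth = 1.5,
                          side = c("left", "right"), slabSpacing = NULL,
                          fill = 0) {
  side <- match.arg(side)
  stopifnot(length(stations) == 2L, all(stations > 0), all(stations < 1))
  list(boneThreshold = boneThreshold, slabThickness = slabThickness,
       inPlaneExtent = inPlaneExtent, headRadiusEst = headRadiusEst,
       headBallFactor = headBallFactor, centerIterations = centerIterations,
       corticalThreshold = corticalThreshold,
       lateralExclusionRadius = lateralExclusionRadius,
       anchorDepth = anchorDepth,
       corridorRange = corridorRange, corridorRadius = corridorRadius,
       calcarOffsetMm = calcarOffsetMm, gtWindow = gtWindow,
       ltWindow = ltWindow, stations = stations, headArcBand = headArcBand,
       openingBand = openingBand, facetDepth = facetDepth, side = side,
       slabSpacing = slabSpacing, fill = fill)
}

# world coordinates of voxels above a threshold
.boneCoords <- function(volume, threshold) {
  idx <- which(volume@values > threshold)
  if (length(idx) == 0L) return(NULL)
  ai <- arrayInd(idx, dim(volume@values))
  W <- (ai - 1) %*% diag(volume@spacing) %*% t(volume@direction)
  sweep(W, 2, volume@origin, "+")
}

#' Align a neck-centered section frame
#'
#' Refines the hinted head center as the iterated centroid of bright voxels
#' in a head-sized ball, then refines the neck direction from the centroid
#' of the lateral neck corridor (bone voxels in a tube around the hinted
#' axis, lateral of the head). Restricting the corridor to the lateral
#' fragment keeps the reference axis independent of the displaced head
#' fragment, mirroring how a radiologist aligns on the intact anatomy. The
#' section normal is the scanner superior axis orthogonalised against the
#' neck axis, so the axial plane contains the neck axis; the frame origin
#' is shifted distally toward the calcar level.
#'
#' @param volume a [CTVolume-class].
#' @param headCenterHint approximate head center, world mm.
#' @param neckDirectionHint approximate neck axis, pointing medially
#'   (toward the head).
#' @param params see [measureParams()].
#' @return a [SectionFrame-class]; \code{meta} holds the refined head
#'   center.
#' @export
alignNeckFrame <- function(volume, headCenterHint, neckDirectionHint,
                           params = measureParams()) {
  stopifnot(is(volume, "CTVolume"))
  headCenterHint <- as.numeric(headCenterHint)
  neckDirectionHint <- as.numeric(neckDirectionHint)
  nh <- sqrt(sum(neckDirectionHint^2))
  if (!is.finite(nh) || nh < 1e-9) stop("neck direction hint must be non-zero")
  dhat <- neckDirectionHint / nh
  W <- .boneCoords(volume, params$boneThreshold)
  if (is.null(W)) stop("no bright voxels in the volume")

  rBall <- params$headBallFactor * params$headRadiusEst
  cen <- headCenterHint
  for (it in seq_len(params$centerIterations)) {
    d2 <- (W[, 1] - cen[1])^2 + (W[, 2] - cen[2])^2 + (W[, 3] - cen[3])^2
    sel <- d2 <= rBall^2
    if (sum(sel) < 10)
      stop("no bright voxels near the head-center hint")
    cen <- colMeans(W[sel, , drop = FALSE])
  }
  # the ball centroid is pulled along the neck by the medial stump; an
  # algebraic sphere fit on the cortical shell is unbiased even though the
  # shell is incomplete at the head-neck aperture
  Wc <- .boneCoords(volume, params$corticalThreshold)
  if (!is.null(Wc)) {
    d2 <- (Wc[, 1] - cen[1])^2 + (Wc[, 2] - cen[2])^2 + (Wc[, 3] - cen[3])^2
    S <- Wc[d2 <= (1.25 * params$headRadiusEst)^2, , drop = FALSE]
    if (nrow(S) >= 30) {
      for (it in 1:4) {
        A <- cbind(2 * S, 1)
        x <- tryCatch(qr.solve(A, rowSums(S^2)), error = function(e) NULL)
        if (is.null(x)) break
        ctr <- x[1:3]
        r <- sqrt(max(x[4] + sum(ctr^2), 0))
        resid <- abs(sqrt(rowSums(sweep(S, 2, ctr)^2)) - r)
        keep <- resid <= max(1.2 * params$headRadiusEst / 20, 2 * median(resid))
        if (sum(keep) < 30 || all(keep)) { cen <- ctr; break }
        S <- S[keep, , drop = FALSE]
        cen <- ctr
      }
    }
  }

  # Refine the neck direction on the lateral fragment only, so the
  # reference axis is independent of the displaced head fragment (the
  # radiologist likewise aligns on the intact lateral anatomy). The lateral
  # fragment is everything beyond a head-sized exclusion ball; its medial
  # tip is the osteotomy face, whose centroid sits on the lateral neck axis
  # by symmetry and anchors a tube that is then iterated around the
  # evolving axis estimate, removing the sensitivity to the hinted
  # direction.
  rel <- sweep(W, 2, cen)
  d2all <- rowSums(rel^2)
  lat <- rel[d2all > params$lateralExclusionRadius^2, , drop = FALSE]
  if (nrow(lat) < 50)
    stop("lateral fragment not found beyond the head exclusion ball")
  latD2 <- rowSums(lat^2)
  u <- dhat
  p1 <- NULL                      # anchor on the lateral neck axis
  cc <- NULL
  for (outer in 1:3) {
    sAll <- as.numeric(-(lat %*% u))
    radial2 <- latD2 - sAll^2
    if (is.null(p1)) {
      # first pass: radial relative to the hinted line through the head
      rp2 <- radial2
    } else {
      relP <- sweep(lat, 2, p1)
      tP <- as.numeric(relP %*% u)
      rp2 <- rowSums(relP^2) - tP^2
    }
    nearAxis <- rp2 <= params$corridorRadius^2
    if (sum(nearAxis) < 20)
      stop("lateral neck corridor is empty; check the neck-direction hint")
    # medial tip of the lateral fragment (the osteotomy face): first 2 mm
    # band along the axis with substantial bone occupancy, so isolated
    # noise voxels medial of the face cannot masquerade as the tip
    sNear <- sAll[nearAxis]
    br <- seq(floor(min(sNear)), ceiling(max(sNear)) + 2, by = 2)
    cnt <- tabulate(findInterval(sNear, br), nbins = length(br))
    need <- max(5, 0.04 * pi * params$corridorRadius^2 * 2 /
                  prod(volume@spacing))
    ok <- which(cnt >= need)
    if (length(ok) == 0)
      stop("lateral neck corridor is empty; check the neck-direction hint")
    sMin <- min(sNear[sNear >= br[min(ok)]])
    anchorSel <- sAll >= sMin - 1 & sAll <= sMin + params$anchorDepth
    if (!is.null(p1))
      anchorSel <- anchorSel & rp2 <= (params$corridorRadius + 2)^2
    p1 <- colMeans(lat[anchorSel, , drop = FALSE])
    win <- sAll >= sMin + params$corridorRange[1] &
      sAll <= sMin + params$corridorRange[2]
    if (sum(win) < 20)
      stop("lateral neck corridor is empty; check the neck-direction hint")
    latW <- lat[win, , drop = FALSE]
    for (it in 1:4) {
      relP <- sweep(latW, 2, p1)
      t <- as.numeric(relP %*% u)
      r2 <- rowSums(relP^2) - t^2
      sel <- r2 <= params$corridorRadius^2
      if (sum(sel) < 20)
        stop("lateral neck corridor is empty; check the neck-direction hint")
      cc <- colMeans(latW[sel, , drop = FALSE])
      u <- p1 - cc
      u <- u / sqrt(sum(u^2))
      if (sum(u * dhat) < 0) u <- -u
    }
  }
  cc <- cc + cen
  p1 <- p1 + cen

  zref <- volume@direction[, 3]
  w <- zref - sum(zref * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-6) stop("neck axis is parallel to the scanner axis")
  w <- w / nw
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  origin <- cen - params$calcarOffsetMm * zref
  SectionFrame(origin = origin, axes = cbind(u, v, w, deparse.level = 0),
               meta = list(headCenter = cen, corridorCentroid = cc))
}

# vectorised trilinear interpolation at world points P (n x 3)
.trilinear <- function(volume, P, fill = 0) {
  dm <- dim(volume@values)
  idx <- sweep(P, 2, volume@origin) %*% volume@direction
  idx <- sweep(idx, 2, volume@spacing, "/")
  out <- rep(NA_real_, nrow(P))
  inside <- idx[, 1] >= 0 & idx[, 1] <= dm[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= dm[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= dm[3] - 1
  if (any(inside)) {
    q <- idx[inside, , drop = FALSE]
    i0 <- pmin(floor(q[, 1]), dm[1] - 2); f1 <- q[, 1] - i0
    j0 <- pmin(floor(q[, 2]), dm[2] - 2); f2 <- q[, 2] - j0
    k0 <- pmin(floor(q[, 3]), dm[3] - 2); f3 <- q[, 3] - k0
    base <- 1 + i0 + dm[1] * (j0 + dm[2] * k0)
    v <- volume@values
    val <-
      (1 - f1) * (1 - f2) * (1 - f3) * v[base] +
      f1 * (1 - f2) * (1 - f3) * v[base + 1] +
      (1 - f1) * f2 * (1 - f3) * v[base + dm[1]] +
      f1 * f2 * (1 - f3) * v[base + 1 + dm[1]] +
      (1 - f1) * (1 - f2) * f3 * v[base + dm[1] * dm[2]] +
      f1 * (1 - f2) * f3 * v[base + 1 + dm[1] * dm[2]] +
      (1 - f1) * f2 * f3 * v[base + dm[1] + dm[1] * dm[2]] +
      f1 * f2 * f3 * v[base + 1 + dm[1] + dm[1] * dm[2]]
    out[inside] <- val
  }
  attr(out, "insideFraction") <- mean(inside)
  out[!inside] <- fill
  out
}

#' Extract the neck-aligned axial slab
#'
#' Resamples a slab of the given thickness around the frame's axial plane
#' and reduces it by mean-intensity projection. In-plane pixel spacing
#' defaults to the finest voxel spacing of the volume.
#'
#' @param volume a [CTVolume-class].
#' @param frame a [SectionFrame-class].
#' @param thickness slab thickness, mm.
#' @param spacing in-plane spacing, mm.
#' @param extent \code{c(s1min, s1max, s2min, s2max)} relative to the frame
#'   origin, mm.
#' @param fill value for samples outside the volume.
#' @return a [Slice2D-class].
#' @export
extractAxialSlab <- function(volume, frame, thickness = 5, spacing = NULL,
                             extent = c(-100, 40, -48, 48), fill = 0) {
  stopifnot(is(volume, "CTVolume"), is(frame, "SectionFrame"))
  if (thickness <= 0) stop("thickness must be positive")
  if (is.null(spacing)) spacing <- min(volume@spacing)
  s1 <- seq(extent[1], extent[2], by = spacing)
  s2 <- seq(extent[3], extent[4], by = spacing)
  u <- frame@axes[, 1]; v <- frame@axes[, 2]; w <- frame@axes[, 3]
  nSub <- max(1L, round(thickness / spacing))
  offs <- if (nSub == 1L) 0 else seq(-thickness / 2, thickness / 2,
                                     length.out = nSub)
  n1 <- length(s1); n2 <- length(s2)
  gx <- outer(s1 * u[1], s2 * v[1], "+")
  gy <- outer(s1 * u[2], s2 * v[2], "+")
  gz <- outer(s1 * u[3], s2 * v[3], "+")
  acc <- matrix(0, n1, n2)
  insideFrac <- 0
  for (off in offs) {
    o <- frame@origin + off * w
    P <- cbind(as.vector(gx) + o[1], as.vector(gy) + o[2],
               as.vector(gz) + o[3])
    val <- .trilinear(volume, P, fill = fill)
    insideFrac <- insideFrac + attr(val, "insideFraction") / length(offs)
    acc <- acc + matrix(val, n1, n2) / length(offs)
  }
  if (insideFrac < 0.05) stop("slab lies outside the volume")
  new("Slice2D", values = acc, s1 = s1, s2 = s2,
      spacing = rep(spacing, 2), frame = frame, slabThickness = thickness)
}

# boundary pixels (4-connectivity against anything not in the component)
.boundaryPoints <- function(lab, label, s1, s2) {
  m <- lab == label
  n1 <- nrow(m); n2 <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-n1, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -n2, drop = FALSE])
  bnd <- m & !(up & dn & lf & rt)
  ai <- which(bnd, arr.ind = TRUE)
  cbind(s1[ai[, 1]], s2[ai[, 2]])
}

#' Extract and label the cortex contours of a slab
#'
#' Thresholds the slab, labels connected components, and partitions
#' boundary pixels into the four landmark sets of the construction: the
#' femoral head arc and the lateral-opening (neck stump) silhouette on the
#' medial fragment, and the greater-trochanter and dorsal
#' (lesser-trochanter) windows on the lateral fragment. Labeling is purely
#' geometric and deterministic: the component containing the head center is
#' medial, the largest remaining component is lateral; medial boundary
#' points are classified by their distance from the head center relative
#' to the estimated head-disk radius, lateral ones by their position along
#' the in-plane neck axis and, for the dorsal set, by side of the head
#' center.
#'
#' @param slice a [Slice2D-class].
#' @param threshold bone threshold; must lie between background and
#'   cortical intensities.
#' @param headCenter2D head center in slab coordinates (s1, s2), mm; by
#'   default the frame's refined head center is projected into the plane.
#' @param params see [measureParams()].
#' @return a list with matrices \code{headArc}, \code{lateralOpening},
#'   \code{gtVentral}, \code{ltDorsal}, \code{lateralAll}, plus the label
#'   matrix, the head-disk radius estimate and the head center used.
#' @export
extractCortexContours <- function(slice, threshold = 150,
                                  headCenter2D = NULL,
                                  params = measureParams()) {
  stopifnot(is(slice, "Slice2D"))
  if (is.null(headCenter2D)) {
    hc3 <- slice@frame@meta$headCenter
    if (is.null(hc3))
      stop("headCenter2D is required when the frame has no refined center")
    headCenter2D <- as.numeric(
      t(slice@frame@axes[, 1:2]) %*% (hc3 - slice@frame@origin))
  }
  mask <- slice@values >= threshold
  if (!any(mask)) stop("no cortex found above the threshold")
  lab <- EBImage::bwlabel(mask)
  ai <- which(mask, arr.ind = TRUE)
  dd <- (slice@s1[ai[, 1]] - headCenter2D[1])^2 +
    (slice@s2[ai[, 2]] - headCenter2D[2])^2
  iNear <- which.min(dd)
  if (sqrt(dd[iNear]) > 0.75 * params$headRadiusEst)
    stop("femoral head not found near the head center")
  medLab <- lab[ai[iNear, 1], ai[iNear, 2]]
  counts <- tabulate(lab[lab > 0])
  counts[medLab] <- 0
  if (all(counts == 0))
    stop("lateral fragment not found (only one component above threshold)")
  latLab <- which.max(counts)

  bndM <- .boundaryPoints(lab, medLab, slice@s1, slice@s2)
  bndL <- .boundaryPoints(lab, latLab, slice@s1, slice@s2)
  relM <- sweep(bndM, 2, headCenter2D)
  dist <- sqrt(rowSums(relM^2))
  medialHalf <- relM[, 1] >= 0          # +s1 points medially
  r0 <- if (any(medialHalf)) median(dist[medialHalf]) else median(dist)
  headArc <- bndM[dist >= params$headArcBand[1] * r0 &
                  dist <= params$headArcBand[2] * r0, , drop = FALSE]
  opening <- bndM[dist > params$openingBand[1] * r0 &
                  dist <= params$openingBand[2] * r0, , drop = FALSE]
  if (nrow(headArc) < 8) stop("femoral head arc not found")
  if (nrow(opening) < 6)
    stop("lateral opening of the femoral head not found")

  ds1 <- bndL[, 1] - headCenter2D[1]
  gtSel <- ds1 >= params$gtWindow[1] & ds1 <= params$gtWindow[2]
  if (!any(gtSel))
    stop("greater trochanter cortex not found in the expected window")
  ventralSign <- if (params$side == "left") 1 else -1
  ltSel <- ds1 >= params$ltWindow[1] & ds1 <= params$ltWindow[2] &
    ventralSign * (bndL[, 2] - headCenter2D[2]) < 0
  if (!any(ltSel))
    stop("lesser trochanter / dorsal neck cortex not found")

  list(headArc = headArc, lateralOpening = opening,
       gtVentral = bndL[gtSel, , drop = FALSE],
       ltDorsal = bndL[ltSel, , drop = FALSE],
       lateralAll = bndL, labels = lab, headDiskRadius = r0,
       headCenter = headCenter2D)
}

# Circle "centered in the lateral opening of the femoral head". The opening
# silhouette consists of the two neck-stump aperture edges plus the cut
# face; an unconstrained least-squares circle is ill-posed along the stump
# axis for such a set, so the circle is inscribed between the two aperture
# edge lines: trim the cut-face points at the far end, split the remainder
# by side of the provisional axis, fit a line to each edge, and center the
# circle on their mid-line at the mean along-axis position. By the stump's
# mirror symmetry the center lies on the medial neck axis.
.openingCircle <- function(pts, headCenter) {
  ctr0 <- colMeans(pts)
  dir0 <- headCenter - ctr0
  dir0 <- dir0 / sqrt(sum(dir0^2))
  rel <- sweep(pts, 2, headCenter)
  s <- as.numeric(-(rel %*% dir0))          # lateral distance along the stump
  keep <- s <= max(s) - 2                   # drop the cut-face chord
  if (sum(keep) < 6) keep <- rep(TRUE, length(s))
  rel <- rel[keep, , drop = FALSE]
  perp <- rel[, 1] * (-dir0[2]) + rel[, 2] * dir0[1]
  fitEdge <- function(side) {
    Q <- rel[side, , drop = FALSE]
    if (nrow(Q) < 3) stop("aperture edge has too few points")
    cc <- colMeans(Q)
    e <- eigen(crossprod(sweep(Q, 2, cc)), symmetric = TRUE)$vectors[, 1]
    if (sum(e * dir0) > 0) e <- -e
    list(point = cc + headCenter, dir = e)
  }
  e1 <- fitEdge(perp > 0)
  e2 <- fitEdge(perp < 0)
  midDir <- e1$dir + e2$dir
  midDir <- midDir / sqrt(sum(midDir^2))
  gapVec <- e2$point - e1$point
  gapPerp <- gapVec - sum(gapVec * midDir) * midDir
  mid <- e1$point + 0.5 * gapVec
  ctr <- colMeans(rel) + headCenter
  along <- sum((ctr - mid) * midDir)
  Circle2D(center = mid + along * midDir,
           radius = max(sqrt(sum(gapPerp^2)) / 2, 1e-3))
}

# Subpixel cortex edge profile: for every slab row with s1 inside s1lim,
# the first threshold crossing scanning from the ventral (fromTop) or
# dorsal side, linearly interpolated between the straddling pixels.
.edgeProfile <- function(slice, threshold, s1lim, fromTop = TRUE) {
  rows <- which(slice@s1 >= s1lim[1] & slice@s1 <= s1lim[2])
  n2 <- length(slice@s2)
  out <- matrix(NA_real_, length(rows), 2)
  for (ii in seq_along(rows)) {
    v <- slice@values[rows[ii], ]
    hit <- which(v >= threshold)
    if (length(hit) == 0) next
    if (fromTop) {
      j <- max(hit)
      if (j >= n2) next
      s2c <- slice@s2[j] + (slice@s2[j + 1] - slice@s2[j]) *
        (v[j] - threshold) / (v[j] - v[j + 1])
    } else {
      j <- min(hit)
      if (j <= 1) next
      s2c <- slice@s2[j] - (slice@s2[j] - slice@s2[j - 1]) *
        (v[j] - threshold) / (v[j] - v[j - 1])
    }
    out[ii, ] <- c(slice@s1[rows[ii]], s2c)
  }
  out[!is.na(out[, 1]), , drop = FALSE]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Measure femoral neck torsion directly from a CT volume
#'
#' Executes the full construction on the neck-aligned axial slab: a
#' supporting tangent along the ventral cortex of the greater trochanter, a
#' parallel line at the dorsal border crossing the lesser trochanter, a
#' best-fitting circle in the femoral head and in its lateral opening
#' (medial axis), two circles inscribed between tangent and parallel
#' (lateral axis), and the signed intersection angle of the two axes.
#' Anteversion is positive. The full construction is returned for audit.
#'
#' @param volume a [CTVolume-class].
#' @param headCenterHint,neckDirectionHint landmark hints in world mm; for
#'   phantom volumes they default to the stored ground truth.
#' @param params see [measureParams()].
#' @return a [TorsionMeasurement-class].
#' @export
measureTorsion <- function(volume, headCenterHint = NULL,
                           neckDirectionHint = NULL,
                           params = measureParams()) {
  gt <- volume@meta$groundTruth
  if (is.null(headCenterHint)) {
    if (is.null(gt)) stop("headCenterHint is required")
    headCenterHint <- gt$headCenter
  }
  if (is.null(neckDirectionHint)) {
    if (is.null(gt)) stop("neckDirectionHint is required")
    neckDirectionHint <- gt$lateralNeckDirMedial
  }
  ventralSign <- if (params$side == "left") 1 else -1

  frame <- .stage("align_neck_frame",
                  alignNeckFrame(volume, headCenterHint, neckDirectionHint,
                                 params))
  slab <- .stage("extract_axial_slab",
                 extractAxialSlab(volume, frame, params$slabThickness,
                                  spacing = params$slabSpacing,
                                  extent = params$inPlaneExtent,
                                  fill = params$fill))
  ct <- .stage("extract_cortex_contours",
               extractCortexContours(slab, params$boneThreshold,
                                     params = params))

  # The tangent is drawn along the ventral trochanteric cortex: start from
  # the supporting line of the contour, then refine its direction by
  # fitting the subpixel cortex profile within facetDepth of the supporting
  # point, as the operator aligns the drawn tangent with the flat anterior
  # cortex rather than with the viewing frame.
  tangent <- .stage("supporting_tangent", {
    t0 <- supportingTangent(ct$gtVentral, c(0, ventralSign))
    prof <- .edgeProfile(slab, params$boneThreshold,
                         ct$headCenter[1] + params$gtWindow,
                         fromTop = ventralSign > 0)
    if (nrow(prof) >= 5) {
      lev <- prof[, 2] * ventralSign
      keep <- lev >= max(lev) - params$facetDepth
      if (sum(keep) >= 5) {
        P <- prof[keep, , drop = FALSE]
        # robust flat-cortex fit: iteratively trim points off the fitted
        # line so the curved shoulders at the facet ends do not tilt the
        # tangent; the flat cortex itself is straight to subpixel accuracy
        for (it in 1:6) {
          b <- cov(P[, 1], P[, 2]) / var(P[, 1])
          a <- mean(P[, 2]) - b * mean(P[, 1])
          resid <- abs(P[, 2] - (a + b * P[, 1]))
          keep2 <- resid <= max(0.1, 2.5 * median(resid))
          if (sum(keep2) < 6 || all(keep2)) break
          P <- P[keep2, , drop = FALSE]
        }
        b <- cov(P[, 1], P[, 2]) / var(P[, 1])
        dir <- c(1, b) / sqrt(1 + b^2)
        if (sum(dir * t0@direction) < 0) dir <- -dir
        lev2 <- P[, 2] * ventralSign
        t0 <- Line2D(point = P[which.max(lev2), ], direction = dir)
      }
    }
    t0
  })
  parallel <- .stage("parallel_line", {
    prof <- .edgeProfile(slab, params$boneThreshold,
                         ct$headCenter[1] + params$ltWindow,
                         fromTop = ventralSign < 0)
    anchor <- if (nrow(prof) >= 1) {
      prof[which.max(prof[, 2] * (-ventralSign)), ]
    } else {
      ct$ltDorsal[which.max(ct$ltDorsal %*% c(0, -ventralSign)), ]
    }
    parallelThroughPoint(tangent, anchor)
  })

  headCircle <- .stage("head_circle", fitCircle(ct$headArc))
  openingCircle <- .stage("head_opening_circle",
                          .openingCircle(ct$lateralOpening, headCircle@center))

  dirT <- tangent@direction
  delta <- parallel@point - tangent@point
  perp <- delta - sum(delta * dirT) * dirT
  gap <- sqrt(sum(perp^2))
  if (gap < 1e-6) stop("[neck_band] tangent and parallel coincide")
  nperp <- perp / gap
  offs <- sweep(ct$lateralAll, 2, tangent@point) %*% nperp
  inBand <- offs > 1e-9 & offs < gap - 1e-9
  if (sum(inBand) < 4) stop("[neck_band] no lateral cortex inside the band")
  bandPts <- ct$lateralAll[inBand, , drop = FALSE]
  tvals <- sweep(bandPts, 2, tangent@point) %*% dirT
  medialT <- tvals[which.max(bandPts[, 1])]
  lateralT <- tvals[which.min(bandPts[, 1])]
  mkNeckCircle <- function(frac) {
    tS <- medialT + frac * (lateralT - medialT)
    anchor <- tangent@point + as.numeric(tS) * dirT + 0.5 * gap * nperp
    inscribedCircleBetweenLines(tangent, parallel, anchor)
  }
  neck1 <- .stage("neck_circle_1", mkNeckCircle(params$stations[1]))
  neck2 <- .stage("neck_circle_2", mkNeckCircle(params$stations[2]))

  medialAxis <- .stage("medial_axis", axisFromCenters(openingCircle, headCircle))
  lateralAxis <- .stage("lateral_axis", axisFromCenters(neck2, neck1))
  pair <- AxisPair(medialAxis = medialAxis, lateralAxis = lateralAxis)
  angle <- .stage("intersection_angle",
                  angleBetweenAxes(pair, c(0, ventralSign)))

  new("TorsionMeasurement", angleDeg = angle,
      circles = list(head = headCircle, headOpening = openingCircle,
                     neck1 = neck1, neck2 = neck2),
      tangent = tangent, parallel = parallel, axes = pair,
      sliceRef = list(frameOrigin = frame@origin, frameAxes = frame@axes,
                      thickness = slab@slabThickness,
                      spacing = slab@spacing, side = params$side),
      slice = slab)
}
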