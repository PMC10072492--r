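# 2D primitives of the direct-measurement construction. All operations are
# purely geometric and equivariant under rigid motions of their inputs.

.rot90ccw <- function(v) c(-v[2], v[1])

.as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(points) <- "double"
  points
}

#' Least-squares circle fit (Pratt algebraic fit, geometrically polished)
#'
#' Fits a circle to 2D points by minimising algebraic residuals of
#' \eqn{A(x^2+y^2) + Bx + Cy + D} under the Pratt normalisation
#' \eqn{B^2 + C^2 - 4AD = 1}, which is stable for partial arcs such as the
#' femoral head seen through its lateral opening, then polishes the result
#' with a few Gauss-Newton steps on the geometric (radial) residuals.
#' Exact for points lying on a circle.
#'
#' @param points n x 2 matrix of points (n >= 3, not collinear), mm.
#' @return a [Circle2D-class].
#' @examples
#' fitCircle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
#' @export
fitCircle <- function(points) {
  points <- .as_points(points)
  n <- nrow(points)
  if (n < 3L) stop("circle fit needs at least 3 points")
  ctr <- colMeans(points)
  x <- points[, 1] - ctr[1]
  y <- points[, 2] - ctr[2]
  sv <- svd(cbind(x, y), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1e-300))
    stop("circle fit is degenerate: points are collinear")
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  S <- crossprod(Z) / n
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4)
  ev <- eigen(solve(B, S))
  vals <- Re(ev$values)
  scale <- max(abs(vals))
  ok <- which(vals > -1e-9 * scale)
  v <- Re(ev$vectors[, ok[which.min(vals[ok])]])
  A <- v[1]
  if (abs(A) < 1e-14 * sqrt(sum(v[2:3]^2)))
    stop("circle fit is degenerate: best algebraic fit is a line")
  cc <- -v[2:3] / (2 * A)
  # Gauss-Newton on the radial residuals (radius profiled out as the mean
  # distance); the algebraic fit is already within O(noise^2) of the
  # optimum, so a handful of steps suffices
  for (it in 1:20) {
    dx <- x - cc[1]; dy <- y - cc[2]
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-12)) break
    ux <- -dx / d; uy <- -dy / d
    e <- d - mean(d)
    jx <- ux - mean(ux); jy <- uy - mean(uy)
    g <- c(sum(jx * e), sum(jy * e))
    H <- matrix(c(sum(jx * jx), sum(jx * jy),
                  sum(jx * jy), sum(jy * jy)), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e2) c(0, 0))
    if (!all(is.finite(step)) || sqrt(sum(step^2)) < 1e-13) break
    cc <- cc - step
  }
  d <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
  Circle2D(center = cc + ctr, radius = mean(d))
}

#' Supporting line of a contour in a given direction
#'
#' Formalisation of the hand-drawn tangent: the supporting line of the
#' contour's convex hull that is extremal in \code{outward}. All contour
#' points lie on the non-outward side; the returned direction is
#' perpendicular to \code{outward} (rotated +90 degrees).
#'
#' @param contour n x 2 matrix of points (n >= 2).
#' @param outward unit 2-vector pointing away from the bone (e.g. ventral
#'   for the greater-trochanter tangent).
#' @return a [Line2D-class] through the extremal point.
#' @export
supportingTangent <- function(contour, outward) {
  contour <- .as_points(contour)
  if (nrow(contour) < 2L) stop("supporting line needs at least 2 points")
  outward <- as.numeric(outward)
  nrm <- sqrt(sum(outward^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("outward direction must be non-zero")
  outward <- outward / nrm
  proj <- contour %*% outward
  i <- which.max(proj)
  Line2D(point = contour[i, ], direction = .rot90ccw(outward))
}

#' Parallel line through a point
#'
#' @param line a [Line2D-class].
#' @param point numeric(2).
#' @return a [Line2D-class] with the same direction through \code{point}.
#' @export
parallelThroughPoint <- function(line, point) {
  stopifnot(is(line, "Line2D"))
  Line2D(point = as.numeric(point), direction = line@direction)
}

#' Circle inscribed between two parallel lines
#'
#' The circle tangent to both lines (radius = half the inter-line distance),
#' centered on the mid-line at the along-line coordinate nearest to
#' \code{station}.
#'
#' @param bandLower,bandUpper parallel [Line2D-class] objects (within 0.5
#'   degrees).
#' @param station numeric(2) anchor point, strictly between the lines.
#' @param parallelTolDeg maximal allowed angle between the lines, degrees.
#' @return a [Circle2D-class].
#' @export
inscribedCircleBetweenLines <- function(bandLower, bandUpper, station,
                                        parallelTolDeg = 0.5) {
  stopifnot(is(bandLower, "Line2D"), is(bandUpper, "Line2D"))
  station <- as.numeric(station)
  u <- bandLower@direction
  u2 <- bandUpper@direction
  cr <- abs(u[1] * u2[2] - u[2] * u2[1])
  if (asin(min(1, cr)) * 180 / pi > parallelTolDeg)
    stop("band lines are not parallel within tolerance")
  delta <- bandUpper@point - bandLower@point
  perp <- delta - sum(delta * u) * u
  gap <- sqrt(sum(perp^2))
  if (gap < 1e-9) stop("band lines coincide; inscribed circle undefined")
  nrm <- perp / gap
  t <- sum((station - bandLower@point) * nrm)
  if (t <= 0 || t >= gap)
    stop("station must lie strictly between the band lines")
  mid <- bandLower@point + 0.5 * gap * nrm
  along <- sum((station - mid) * u)
  Circle2D(center = mid + along * u, radius = gap / 2)
}

#' Axis through two circle centers
#'
#' @param c1,c2 [Circle2D-class] objects with distinct centers; the
#'   direction points from \code{c1} to \code{c2}.
#' @return a [Line2D-class] through both centers.
#' @export
axisFromCenters <- function(c1, c2) {
  stopifnot(is(c1, "Circle2D"), is(c2, "Circle2D"))
  d <- c2@center - c1@center
  if (sqrt(sum(d^2)) <= 1e-6)
    stop("circle centers coincide; axis undefined")
  Line2D(point = c1@center, direction = d)
}

#' Signed acute angle between the neck axes
#'
#' Returns the acute intersection angle in degrees between the medial and
#' lateral axes, signed positive when the medial axis is rotated toward
#' \code{signReference} (the ventral direction) relative to the lateral
#' axis: anteversion positive, retroversion negative. The medial direction
#' is first oriented to agree with the lateral one (positive dot product),
#' so callers should store both axis directions pointing the same
#' anatomical way (medially, in [measureTorsion()]).
#'
#' @param pair an [AxisPair-class].
#' @param signReference unit 2-vector (ventral).
#' @return signed degrees, magnitude in [0, 90].
#' @export
angleBetweenAxes <- function(pair, signReference) {
  stopifnot(is(pair, "AxisPair"))
  signReference <- as.numeric(signReference)
  nrm <- sqrt(sum(signReference^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("signReference must be non-zero")
  signReference <- signReference / nrm
  am <- pair@medialAxis@direction
  al <- pair@lateralAxis@direction
  if (sum(am * al) < 0) am <- -am
  dp <- sum(am * al)
  cr <- al[1] * am[2] - al[2] * am[1]
  mag <- atan2(abs(cr), abs(dp)) * 180 / pi
  if (mag == 0) return(0)
  perp <- am - dp * al
  s <- sum(perp * signReference)
  if (s == 0) mag else sign(s) * mag
}
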