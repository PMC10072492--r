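test_that("circle fit recovers exact circles and the circumcircle", {
  c1 <- fitCircle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(c1@center, c(0, 0), tolerance = 1e-9)
  expect_equal(c1@radius, 1, tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 101)[-101]
  pts <- cbind(3 + 5 * cos(th), -2 + 5 * sin(th))
  c2 <- fitCircle(pts)
  expect_lt(max(abs(c2@center - c(3, -2))), 1e-9)
  expect_lt(abs(c2@radius - 5), 1e-9)
})

test_that("circle fit matches the grid-search oracle on noisy data", {
  set.seed(7)
  th <- runif(50, 0, 2 * pi)
  pts <- cbind(5 * cos(th), 5 * sin(th)) + matrix(rnorm(100, sd = 0.1), 50)
  fit <- fitCircle(pts)
  oracle <- gridSearchCircle(pts)
  expect_lt(sqrt(sum((fit@center - oracle$center)^2)), 2e-2)
  # the fit's geometric residual never beats the oracle by more than the
  # grid resolution, and never exceeds it by more than 1e-6
  d <- sqrt(rowSums(sweep(pts, 2, fit@center)^2))
  ssFit <- sum((d - mean(d))^2)
  expect_lt(ssFit, oracle$ss + 1e-6)
})

test_that("circle fit rejects degenerate input", {
  expect_error(fitCircle(rbind(c(0, 0), c(1, 1))), "3 points")
  expect_error(fitCircle(cbind(1:10, 2 * (1:10) + 1)), "collinear")
})

test_that("supporting tangent touches the extremal point, all points one side", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  ln <- supportingTangent(sq, c(0, 1))
  expect_equal(ln@point[2], 1)
  expect_equal(abs(ln@direction), c(1, 0))

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(2 * cos(th), 2 * sin(th))
  tg <- supportingTangent(circ, c(0, 1))
  # distance from center to tangent equals the radius
  n <- c(-tg@direction[2], tg@direction[1])
  expect_equal(abs(sum((c(0, 0) - tg@point) * n)), 2, tolerance = 1e-6)
  proj <- circ %*% c(0, 1)
  expect_true(all(proj <= sum(tg@point * c(0, 1)) + 1e-9))
})

test_that("supporting tangent agrees with exhaustive hull search", {
  set.seed(3)
  for (rep in 1:5) {
    ang <- sort(runif(20, 0, 2 * pi))
    pts <- cbind(cos(ang), sin(ang)) * runif(1, 1, 4) +
      matrix(rep(rnorm(2), each = 20), 20)
    outward <- rnorm(2); outward <- outward / sqrt(sum(outward^2))
    tg <- supportingTangent(pts, outward)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    best <- hull[which.max(hull %*% outward), ]
    expect_equal(sum(tg@point * outward), sum(best * outward),
                 tolerance = 1e-12)
    expect_equal(abs(sum(tg@direction * outward)), 0, tolerance = 1e-12)
  }
})

test_that("parallel line keeps direction and passes through the point", {
  base <- Line2D(c(0, 0), c(1, 0))
  p <- parallelThroughPoint(base, c(0, -5))
  expect_equal(p@point, c(0, -5))
  expect_equal(p@direction, c(1, 0))
  same <- parallelThroughPoint(base, c(3, 0))
  expect_equal(same@direction, base@direction)
  a <- parallelThroughPoint(base, c(1, 7))
  b <- parallelThroughPoint(base, c(-2, 3))
  expect_equal(a@direction[1] * b@direction[2] -
                 a@direction[2] * b@direction[1], 0)
})

test_that("inscribed circle halves the band and respects the station", {
  l0 <- Line2D(c(0, 0), c(1, 0))
  l4 <- Line2D(c(0, 4), c(1, 0))
  ic <- inscribedCircleBetweenLines(l0, l4, c(7, 1))
  expect_equal(ic@center, c(7, 2))
  expect_equal(ic@radius, 2)
  for (st in list(c(-3, 0.5), c(0, 3.9), c(100, 2)))
    expect_equal(inscribedCircleBetweenLines(l0, l4, st)@radius, 2)
  expect_error(inscribedCircleBetweenLines(l0, l4, c(0, 5)), "between")
  expect_error(inscribedCircleBetweenLines(l0, Line2D(c(0, 4), c(1, 0.1)),
                                           c(0, 2)), "parallel")
})

test_that("inscribed circle is equivariant under rigid motion", {
  l0 <- Line2D(c(0, 0), c(1, 0))
  l4 <- Line2D(c(0, 4), c(1, 0))
  st <- c(7, 1)
  base <- inscribedCircleBetweenLines(l0, l4, st)
  R <- rot2d(30)
  rl <- function(l) Line2D(as.numeric(R %*% l@point),
                           as.numeric(R %*% l@direction))
  rot <- inscribedCircleBetweenLines(rl(l0), rl(l4), as.numeric(R %*% st))
  expect_equal(rot@center, as.numeric(R %*% base@center), tolerance = 1e-8)
  expect_equal(rot@radius, base@radius, tolerance = 1e-12)
})

test_that("axis through centers behaves symmetrically", {
  ca <- Circle2D(c(0, 0), 1); cb <- Circle2D(c(1, 0), 1)
  expect_equal(axisFromCenters(ca, cb)@direction, c(1, 0))
  cc <- Circle2D(c(0, 3), 1)
  expect_equal(axisFromCenters(ca, cc)@direction, c(0, 1))
  fwd <- axisFromCenters(ca, cb); bwd <- axisFromCenters(cb, ca)
  expect_equal(abs(sum(fwd@direction * bwd@direction)), 1, tolerance = 1e-12)
  expect_error(axisFromCenters(ca, Circle2D(c(0, 1e-9), 1)), "coincide")
})

test_that("signed angle between axes follows the anteversion convention", {
  lat <- Line2D(c(0, 0), c(1, 0))
  par <- Line2D(c(0, 2), c(1, 0))    # parallel but distinct
  expect_equal(angleBetweenAxes(AxisPair(par, lat), c(0, 1)), 0)
  expect_error(AxisPair(lat, lat), "identical")
  perp <- Line2D(c(0, 0), c(0, 1))
  expect_equal(abs(angleBetweenAxes(AxisPair(perp, lat), c(0, 1))), 90)
  med <- Line2D(c(0, 0), as.numeric(rot2d(17.3) %*% c(1, 0)))
  expect_equal(angleBetweenAxes(AxisPair(med, lat), c(0, 1)), 17.3,
               tolerance = 1e-9)
  # swapping medial and lateral negates the signed angle
  expect_equal(angleBetweenAxes(AxisPair(lat, med), c(0, 1)), -17.3,
               tolerance = 1e-9)
})

test_that("constructions are equivariant under global rigid motion", {
  set.seed(9)
  th <- runif(40, 0.3, 2 * pi - 0.3)
  arc <- cbind(4 + 2 * cos(th), -1 + 2 * sin(th))
  for (rep in 1:5) {
    deg <- runif(1, -180, 180); shift <- rnorm(2, sd = 10)
    f0 <- fitCircle(arc)
    f1 <- fitCircle(applyRigid2d(arc, deg, shift))
    expect_lt(max(abs(f1@center -
                        applyRigid2d(rbind(f0@center), deg, shift))), 1e-8)
    expect_lt(abs(f1@radius - f0@radius), 1e-8)

    outward <- c(0, 1)
    t0 <- supportingTangent(arc, outward)
    t1 <- supportingTangent(applyRigid2d(arc, deg, shift),
                            as.numeric(rot2d(deg) %*% outward))
    expect_lt(max(abs(t1@point -
                        applyRigid2d(rbind(t0@point), deg, shift))), 1e-8)
    expect_lt(max(abs(t1@direction -
                        as.numeric(rot2d(deg) %*% t0@direction))), 1e-8)

    # the signed angle is invariant when every element is moved together
    medDir <- as.numeric(rot2d(23) %*% c(1, 0))
    pair <- AxisPair(Line2D(c(0, 0), medDir), Line2D(c(0, 0), c(1, 0)))
    rpair <- AxisPair(Line2D(shift, as.numeric(rot2d(deg) %*% medDir)),
                      Line2D(shift, as.numeric(rot2d(deg) %*% c(1, 0))))
    expect_equal(angleBetweenAxes(rpair, as.numeric(rot2d(deg) %*% c(0, 1))),
                 angleBetweenAxes(pair, c(0, 1)), tolerance = 1e-8)
  }
})
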