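# pipeline tests run on coarse (1.2 mm) phantoms for speed; the acceptance
# suite exercises the full 0.8 mm study conditions

test_that("frame alignment recovers the ground-truth axes from hints", {
  vol <- buildPhantom(PhantomSpec(setAngle = 0, voxelSpacing = rep(1, 3),
                                  noiseSd = 0))
  gt <- groundTruth(vol)
  fr <- alignNeckFrame(vol, gt$headCenter, gt$lateralNeckDirMedial)
  expect_lt(acos(min(1, sum(frameAxes(fr)[, 1] * gt$lateralNeckDirMedial))) *
              180 / pi, 1)
  # exact hints are left essentially in place (< 0.5 voxel)
  expect_lt(sqrt(sum((fr@meta$headCenter - gt$headCenter)^2)),
            0.5 * max(voxelSpacing(vol)))
  expect_error(alignNeckFrame(vol, c(500, 500, 500), c(1, 0, 0)),
               "head-center hint")
})

test_that("frame alignment is equivariant under a world rotation", {
  vol <- cachedPhantom(10, noiseSd = 0)
  gt <- groundTruth(vol)
  fr0 <- alignNeckFrame(vol, gt$headCenter, gt$lateralNeckDirMedial)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  volR <- CTVolume(values = volumeArray(vol), spacing = voxelSpacing(vol),
                   origin = as.numeric(Rz %*% vol@origin),
                   direction = Rz %*% vol@direction, meta = vol@meta)
  frR <- alignNeckFrame(volR, as.numeric(Rz %*% gt$headCenter),
                        as.numeric(Rz %*% gt$lateralNeckDirMedial))
  expect_lt(max(abs(frameAxes(frR) - Rz %*% frameAxes(fr0))), 1e-6)
  expect_lt(max(abs(frameOrigin(frR) - as.numeric(Rz %*% frameOrigin(fr0)))),
            1e-6)
})

test_that("axial slab projection behaves on analytic inputs", {
  # a uniform volume projects to a uniform slice
  uni <- CTVolume(array(7, c(30, 30, 30)), spacing = rep(1, 3),
                  origin = c(-15, -15, -15))
  fr <- SectionFrame(c(0, 0, 0), diag(3))
  sl <- extractAxialSlab(uni, fr, thickness = 5, extent = c(-8, 8, -8, 8))
  expect_equal(range(sl@values), c(7, 7))

  # one-voxel thickness equals a single-plane resample
  s1 <- extractAxialSlab(uni, fr, thickness = 1, extent = c(-8, 8, -8, 8))
  s2 <- extractAxialSlab(uni, fr, thickness = 1e-9, extent = c(-8, 8, -8, 8))
  expect_equal(s1@values, s2@values)

  # a sphere projects to a disk of its equatorial radius (within 1 voxel)
  g <- seq(-15, 14, by = 1)
  ball <- array(0, c(30, 30, 30))
  for (k in seq_along(g)) {
    r2 <- outer((g + 0.0)^2, (g + 0.0)^2, "+") + g[k]^2
    ball[, , k] <- ifelse(r2 <= 100, 1000, 0)
  }
  vol <- CTVolume(ball, spacing = rep(1, 3), origin = c(-15, -15, -15))
  sl <- extractAxialSlab(vol, fr, thickness = 5, extent = c(-14, 14, -14, 14))
  mid <- which.min(abs(sl@s2))
  width <- range(sl@s1[sl@values[, mid] >= 500])
  expect_lte(abs(width[2] - 10), 1)
  expect_lte(abs(width[1] + 10), 1)

  expect_error(extractAxialSlab(uni, SectionFrame(c(1e4, 0, 0), diag(3)),
                                extent = c(-8, 8, -8, 8)), "outside")
})

test_that("cortex contours label the landmarks of the construction", {
  vol <- cachedPhantom(0, noiseSd = 0)
  gt <- groundTruth(vol)
  fr <- alignNeckFrame(vol, gt$headCenter, gt$lateralNeckDirMedial)
  sl <- extractAxialSlab(vol, fr, 5, extent = c(-100, 40, -48, 48))
  ct <- extractCortexContours(sl, 150)
  for (nm in c("headArc", "lateralOpening", "gtVentral", "ltDorsal"))
    expect_gt(nrow(ct[[nm]]), 0)

  # head-arc points lie on the ground-truth head disk (within ~1 voxel)
  hc2 <- as.numeric(t(frameAxes(fr)[, 1:2]) %*% (gt$headCenter - fr@origin))
  off <- sum((gt$headCenter - fr@origin) * frameAxes(fr)[, 3])
  rdisk <- sqrt(gt$headRadius^2 - off^2)
  d <- sqrt(rowSums(sweep(ct$headArc, 2, hc2)^2))
  expect_lt(max(abs(d - rdisk)), 1.5 * max(voxelSpacing(vol)))

  expect_error(extractCortexContours(sl, 5000), "no cortex")
})

test_that("contour labeling is stable under image noise", {
  volQuiet <- cachedPhantom(10, noiseSd = 0)
  volNoisy <- buildPhantom(coarseSpec(10, noiseSd = 60, seed = 2))
  a0 <- torsionAngle(measureTorsion(volQuiet))
  a1 <- torsionAngle(measureTorsion(volNoisy))
  expect_lt(abs(a1 - a0), 1)
})

test_that("null displacement measures near zero and is deterministic", {
  vol <- cachedPhantom(0, noiseSd = 0)
  m1 <- measureTorsion(vol)
  expect_lte(abs(torsionAngle(m1)), 1)
  m2 <- measureTorsion(vol)
  expect_identical(torsionAngle(m1), torsionAngle(m2))
  expect_identical(m1@circles$head@center, m2@circles$head@center)
  expect_identical(m1@tangent@direction, m2@tangent@direction)
})

test_that("a 10 degree displacement lands in the published measured range", {
  vol <- buildPhantom(PhantomSpec(setAngle = 10,
                                  voxelSpacing = rep(0.8, 3), seed = 3))
  a <- torsionAngle(measureTorsion(vol))
  expect_gte(a, 9.60)
  expect_lte(a, 12.40)
})

test_that("measured angles increase strictly with the set angle", {
  a <- vapply(c(-30, -20, -10, 10, 20, 30),
              function(th) torsionAngle(measureTorsion(cachedPhantom(th))),
              0)
  expect_true(all(diff(a) > 0))
})

test_that("a mirrored (right) femur yields the same anteversion", {
  vl <- buildPhantom(coarseSpec(20, noiseSd = 0))
  vr <- buildPhantom(coarseSpec(20, noiseSd = 0, side = "right"))
  al <- torsionAngle(measureTorsion(vl))
  ar <- torsionAngle(measureTorsion(vr, params = measureParams(side = "right")))
  # mirrored geometry with the mirrored sign convention gives the same
  # anteversion; keeping the left-femur sign reference on the mirrored
  # construction is exactly a sign flip of the reported angle
  expect_lt(abs(al - ar), 0.2)
})

test_that("stage failures are tagged with the failing construction step", {
  vol <- cachedPhantom(0, noiseSd = 0)
  err <- tryCatch(measureTorsion(vol, headCenterHint = c(500, 500, 500),
                                 neckDirectionHint = c(1, 0, 0)),
                  error = conditionMessage)
  expect_match(err, "\\[align_neck_frame\\]")
})
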