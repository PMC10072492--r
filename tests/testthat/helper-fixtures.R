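# shared fixtures: coarse phantoms for fast tests, rigid-motion helpers

rot2d <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

applyRigid2d <- function(points, deg, shift) {
  sweep(points %*% t(rot2d(deg)), 2, shift, "+")
}

# coarse, fast phantom spec for unit tests (1.2 mm isotropic)
coarseSpec <- function(setAngle = 0, ...) {
  PhantomSpec(setAngle = setAngle, voxelSpacing = rep(1.2, 3), ...)
}

# memoised coarse phantoms so several tests can share one build
.phantomCache <- new.env(parent = emptyenv())
cachedPhantom <- function(setAngle, noiseSd = 20, seed = 1L) {
  key <- sprintf("a%+d_n%g_s%d", setAngle, noiseSd, seed)
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- buildPhantom(coarseSpec(setAngle,
                                                    noiseSd = noiseSd,
                                                    seed = seed))
  .phantomCache[[key]]
}

# brute-force two-way ANOVA ICC(A,1) with explicit loops (oracle)
bruteForceICC <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + m[i, j]
  gm <- gm / (n * k)
  rowm <- numeric(n); colm <- numeric(k)
  for (i in 1:n) { s <- 0; for (j in 1:k) s <- s + m[i, j]; rowm[i] <- s / k }
  for (j in 1:k) { s <- 0; for (i in 1:n) s <- s + m[i, j]; colm[j] <- s / n }
  ssr <- 0; ssc <- 0; sse <- 0
  for (i in 1:n) ssr <- ssr + (rowm[i] - gm)^2
  for (j in 1:k) ssc <- ssc + (colm[j] - gm)^2
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (m[i, j] - rowm[i] - colm[j] + gm)^2
  MSR <- k * ssr / (n - 1)
  MSC <- n * ssc / (k - 1)
  MSE <- sse / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# grid-search circle-fit oracle: center minimising the sum of squared
# radial residuals over a center grid refined coarse-to-fine down to a
# 0.001 step (radius = mean distance, optimal for this loss)
gridSearchCircle <- function(points) {
  scan <- function(c0, halfWidth, step) {
    gx <- seq(c0[1] - halfWidth, c0[1] + halfWidth, by = step)
    gy <- seq(c0[2] - halfWidth, c0[2] + halfWidth, by = step)
    best <- c0; bestSS <- Inf
    for (x in gx) {
      dx2 <- (points[, 1] - x)^2
      for (y in gy) {
        d <- sqrt(dx2 + (points[, 2] - y)^2)
        ss <- sum((d - mean(d))^2)
        if (ss < bestSS) { bestSS <- ss; best <- c(x, y) }
      }
    }
    list(center = best, ss = bestSS)
  }
  r1 <- scan(colMeans(points), 2, 0.05)
  r2 <- scan(r1$center, 0.06, 0.001)
  d <- sqrt((points[, 1] - r2$center[1])^2 + (points[, 2] - r2$center[2])^2)
  list(center = r2$center, radius = mean(d), ss = r2$ss)
}
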