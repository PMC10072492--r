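test_that("descriptives match hand computations", {
  series <- data.frame(rater = 1, replicate = 1:4, set_angle_deg = 10,
                       measured_angle_deg = c(1, 2, 3, 4))
  d <- seriesDescriptives(series)
  expect_equal(d$mean, 2.5)
  expect_equal(d$sd, 1.290994, tolerance = 1e-6)
  expect_equal(d$variance, 1.666667, tolerance = 1e-6)

  const <- data.frame(rater = 1, replicate = 1:3, set_angle_deg = 0,
                      measured_angle_deg = c(5, 5, 5))
  dc <- seriesDescriptives(const)
  expect_equal(dc$sd, 0)
  expect_equal(dc$variance, 0)

  set.seed(2)
  rnd <- data.frame(rater = rep(1:2, each = 6), replicate = rep(1:3, 4),
                    set_angle_deg = rep(rep(c(-10, 10), each = 3), 2),
                    measured_angle_deg = rnorm(12))
  dr <- seriesDescriptives(rnd)
  expect_equal(dr$variance, dr$sd^2, tolerance = 1e-12)

  bad <- data.frame(rater = 1, replicate = 1, set_angle_deg = 0,
                    measured_angle_deg = 1)
  expect_error(seriesDescriptives(bad), "at least 2")
})

test_that("ICC(A,1) handles perfect and offset agreement correctly", {
  m <- cbind(c(1, 2, 3, 4, 7), c(1, 2, 3, 4, 7))
  r <- iccAbsoluteAgreement(m)
  expect_true(r@degenerate)
  expect_equal(iccEstimate(r), 1)

  m2 <- cbind(c(-30, -20, -10, 10, 20, 30),
              c(-30, -20, -10, 10, 20, 30) + 5)
  r2 <- iccAbsoluteAgreement(m2)
  expect_lt(iccEstimate(r2), 1)
  # a constant offset is penalised relative to the consistency flavor
  n <- nrow(m2); k <- ncol(m2)
  rowm <- rowMeans(m2); colm <- colMeans(m2); gm <- mean(m2)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSE <- sum((m2 - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2) / ((n - 1) * (k - 1))
  iccConsistency <- (MSR - MSE) / (MSR + (k - 1) * MSE)
  expect_lt(iccEstimate(r2), iccConsistency)
})

test_that("ICC matches the brute-force ANOVA oracle to 1e-10", {
  set.seed(31)
  for (rep in 1:10) {
    m <- matrix(rnorm(12, 10, 5), 6, 2)
    expect_equal(iccEstimate(iccAbsoluteAgreement(m)), bruteForceICC(m),
                 tolerance = 1e-10)
    m3 <- matrix(rnorm(30, 0, 3), 10, 3)
    expect_equal(iccEstimate(iccAbsoluteAgreement(m3)), bruteForceICC(m3),
                 tolerance = 1e-10)
  }
})

test_that("ICC estimate, CI and p agree with reference software values", {
  # frozen reference values computed with pingouin's ICC2 on these data
  set.seed(11)
  m <- matrix(round(rnorm(12, 10, 5), 2), 6, 2)
  r <- iccAbsoluteAgreement(m)
  expect_equal(iccEstimate(r), -0.029844, tolerance = 1e-5)
  expect_equal(r@p, 0.524315, tolerance = 1e-5)
  expect_equal(round(r@ciLow, 2), -0.83)
  expect_equal(round(r@ciHigh, 2), 0.75)

  m2 <- matrix(c(-30, -20, -10, 10, 20, 30, -25, -19, -12, 14, 19, 31), 6, 2)
  r2 <- iccAbsoluteAgreement(m2)
  expect_equal(iccEstimate(r2), 0.992647, tolerance = 1e-5)
  expect_equal(r2@p, 3.737675e-06, tolerance = 1e-4)
  expect_equal(round(r2@ciLow, 2), 0.96)
  expect_equal(round(r2@ciHigh, 2), 1)

  expect_error(iccAbsoluteAgreement(cbind(c(1, NA), c(1, 2))), "missing")
  expect_error(iccAbsoluteAgreement(matrix(1, 1, 2)), "at least 2")
})

test_that("simulated two-rater series give near-perfect ICC", {
  iccs <- vapply(1:30, function(s) {
    ser <- simulateGoniometerSeries(replicates = 2, raters = 2,
                                    raterNoiseSd = 1.5, seed = s)
    m <- sapply(1:2, function(r)
      vapply(c(-30, -20, -10, 10, 20, 30), function(lv)
        ser$measured_angle_deg[ser$rater == r & ser$set_angle_deg == lv &
                                 ser$replicate == 1][1], 0))
    iccEstimate(iccAbsoluteAgreement(m))
  }, 0)
  expect_gte(median(iccs), 0.98)
})

test_that("Pearson correlation matches hand computation", {
  x <- 1:5
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  p <- pearsonCorrelation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(p$r, 0.8, tolerance = 1e-12)
  expect_equal(p$p, 0.104, tolerance = 1e-3)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("paired t-test reproduces printed summaries and raw data equally", {
  # summary path against a published-style (mean, sd, n) row
  r <- pairedTTest(mean = -0.24, sd = 3.24, n = 10)
  expect_equal(round(r@ciLow, 2), -2.56)
  expect_equal(round(r@ciHigh, 2), 2.08)
  expect_equal(round(r@p, 3), 0.82)

  sym <- pairedTTest(diff = c(rep(1, 5), rep(-1, 5)))
  expect_equal(sym@meanDiff, 0)
  expect_equal(sym@ciLow, -sym@ciHigh)

  raw <- pairedTTest(diff = c(1, 2, 3, 4))
  summ <- pairedTTest(mean = 2.5, sd = sd(c(1, 2, 3, 4)), n = 4)
  expect_equal(raw@t, summ@t, tolerance = 1e-9)
  expect_equal(raw@ciLow, summ@ciLow, tolerance = 1e-9)
  expect_equal(raw@p, summ@p, tolerance = 1e-9)
  # and against the standard implementation
  tt <- t.test(c(1, 2, 3, 4))
  expect_equal(raw@t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw@p, tt$p.value, tolerance = 1e-12)
  expect_equal(raw@ciLow, tt$conf.int[1], tolerance = 1e-12)

  expect_error(pairedTTest(diff = c(2, 2, 2)), "degenerate")
})

test_that("validation battery reproduces the published analysis shape", {
  ser <- simulateGoniometerSeries(replicates = 10, raters = 2,
                                  raterBias = c(0, 0.5),
                                  raterNoiseSd = 1.5, seed = 12)
  rep1 <- runValidationBattery(ser)
  expect_named(rep1, c("descriptives", "reliability", "reliabilityPooled",
                       "pairedTests"))
  expect_equal(nrow(rep1$descriptives), 12)       # 2 raters x 6 levels
  expect_equal(nrow(rep1$reliability), 10)        # one row per replicate
  expect_equal(nrow(rep1$pairedTests), 6)         # one row per level
  expect_true(all(c("icc", "ciLow", "ciHigh", "pearsonR") %in%
                    names(rep1$reliability)))

  # order invariance
  shuffled <- ser[sample.int(nrow(ser)), ]
  rep2 <- runValidationBattery(shuffled)
  expect_equal(rep1$reliability$icc, rep2$reliability$icc)
  expect_equal(rep1$pairedTests$meanDiff, rep2$pairedTests$meanDiff)

  # noiseless series: exact agreement everywhere
  ser0 <- simulateGoniometerSeries(replicates = 3, raters = 2,
                                   raterNoiseSd = 0, seed = 1)
  rep0 <- runValidationBattery(ser0)
  expect_true(all(rep0$reliability$degenerate))
  expect_true(all(rep0$reliability$icc == 1))
  expect_true(all(rep0$pairedTests$agreementExact))
  expect_true(all(rep0$pairedTests$meanDiff == 0))

  # ICC and Pearson nearly agree without bias, diverge under bias
  serNoBias <- simulateGoniometerSeries(replicates = 10, raters = 2,
                                        raterNoiseSd = 1.5, seed = 5)
  bNo <- runValidationBattery(serNoBias)
  expect_lt(abs(bNo$reliabilityPooled$icc[1] -
                  bNo$reliabilityPooled$pearsonR[1]), 0.02)
  serBias <- simulateGoniometerSeries(replicates = 10, raters = 2,
                                      raterBias = c(0, 6),
                                      raterNoiseSd = 1.5, seed = 5)
  bBias <- runValidationBattery(serBias)
  expect_lt(bBias$reliabilityPooled$icc[1], bBias$reliabilityPooled$pearsonR[1])
})
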