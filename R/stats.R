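# Reliability statistics: per-level descriptives, ICC(A,1) with the
# F-based confidence interval, Pearson correlation, paired t-tests.

.checkSeries <- function(series) {
  need <- c("rater", "replicate", "set_angle_deg", "measured_angle_deg")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(series$measured_angle_deg)))
    stop("measured angles must be finite")
  invisible(series)
}

#' Per-level descriptive statistics
#'
#' Minimum, maximum, mean, sample standard deviation and variance of the
#' measured angle for every (rater, set level) cell.
#'
#' @param series a measurement series (see [simulateGoniometerSeries()]).
#' @return a \code{data.frame} with one row per (rater, level).
#' @export
seriesDescriptives <- function(series) {
  .checkSeries(series)
  key <- interaction(series$rater, series$set_angle_deg, drop = TRUE)
  cells <- split(series$measured_angle_deg, key)
  if (any(vapply(cells, length, 1L) < 2))
    stop("every (rater, level) cell needs at least 2 values")
  info <- unique(series[, c("rater", "set_angle_deg")])
  info <- info[order(info$rater, info$set_angle_deg), ]
  out <- do.call(rbind, lapply(seq_len(nrow(info)), function(i) {
    x <- series$measured_angle_deg[series$rater == info$rater[i] &
                                   series$set_angle_deg ==
                                     info$set_angle_deg[i]]
    data.frame(rater = info$rater[i], set_angle_deg = info$set_angle_deg[i],
               n = length(x), min = min(x), max = max(x), mean = mean(x),
               sd = sd(x), variance = sd(x)^2)
  }))
  rownames(out) <- NULL
  out
}

#' Single-measures absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way model with absolute agreement, single measures: from the ANOVA
#' decomposition with row (subject) mean square MSR, column (rater) mean
#' square MSC and residual MSE,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' The confidence interval uses the F-distribution approach of McGraw and
#' Wong with a Satterthwaite df for the mixed term; the p-value tests
#' ICC = 0 via F = MSR/MSE on (n-1, (n-1)(k-1)) df, as reliability software
#' reports for this model. When the error and rater variances are exactly
#' zero (identical columns), exact agreement is reported with the
#' \code{degenerate} flag instead of an undefined F ratio.
#'
#' @param m numeric matrix, n subjects x k raters, no missing cells.
#' @param alpha two-tailed level for the confidence interval.
#' @return an [ICCResult-class].
#' @export
iccAbsoluteAgreement <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (any(!is.finite(m)))
    stop("ICC requires a complete (balanced) matrix with no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  rowm <- rowMeans(m); colm <- colMeans(m); gm <- mean(m)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  resid <- m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + gm
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))

  scale <- mean(m^2) + 1e-300
  if (MSE / scale < 1e-14 && MSC / scale < 1e-14) {
    return(new("ICCResult", icc = 1, ciLow = 1, ciHigh = 1, p = 0,
               model = "two-way mixed, absolute agreement, single measures",
               nSubjects = as.integer(n), kRaters = as.integer(k),
               degenerate = TRUE))
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  p <- pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  new("ICCResult", icc = icc, ciLow = min(lower, icc),
      ciHigh = min(1, max(upper, icc)), p = p,
      model = "two-way mixed, absolute agreement, single measures",
      nSubjects = as.integer(n), kRaters = as.integer(k), degenerate = FALSE)
}

#' Pearson correlation with a two-tailed p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with \code{r} and \code{p}.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test from raw differences or printed summaries
#'
#' Computes \eqn{t = \bar d / (s_d/\sqrt n)} with df = n - 1, the two-tailed
#' p-value and the confidence interval
#' \eqn{\bar d \pm t_{1-\alpha/2, n-1} \, s_d/\sqrt n}. Either raw paired
#' differences or a printed summary (mean, sd, n) can be supplied, so
#' published tables can be checked without the raw data.
#'
#' @param diff numeric vector of paired differences, or NULL.
#' @param mean,sd,n summary of the differences when \code{diff} is NULL.
#' @param conf confidence level.
#' @return a [PairedTestResult-class].
#' @export
pairedTTest <- function(diff = NULL, mean = NULL, sd = NULL, n = NULL,
                        conf = 0.95) {
  if (!is.null(diff)) {
    n <- length(diff)
    if (n < 2) stop("need at least 2 paired differences")
    mean <- base::mean(diff)
    sd <- stats::sd(diff)
  } else if (is.null(mean) || is.null(sd) || is.null(n)) {
    stop("supply either raw differences or (mean, sd, n)")
  }
  if (n < 2) stop("need n >= 2")
  if (sd <= 0) stop("zero standard deviation: paired t-test is degenerate")
  se <- sd / sqrt(n)
  t <- mean / se
  df <- n - 1
  p <- 2 * pt(-abs(t), df)
  half <- qt(1 - (1 - conf) / 2, df) * se
  new("PairedTestResult", meanDiff = mean, sdDiff = sd, ciLow = mean - half,
      ciHigh = mean + half, t = t, df = df, p = p)
}

#' Run the full reliability battery on a measurement series
#'
#' Reproduces the shape of a two-rater validation analysis: per (rater,
#' level) descriptives; per-replicate ICC(A,1) and Pearson correlation
#' across the displacement levels (one row per "investigation"), plus a
#' pooled ICC over all (level, replicate) pairs and the mean of the
#' per-replicate ICCs (both labeled, since "mean of all" is ambiguous);
#' and a per-level paired t-test between the first two raters across
#' replicates. Zero-variance cells are reported as exact agreement with a
#' flag rather than undefined statistics.
#'
#' @param series a balanced two-rater measurement series.
#' @param conf confidence level for the paired tests.
#' @return a list of class \code{neckValidationReport} with elements
#'   \code{descriptives}, \code{reliability}, \code{reliabilityPooled},
#'   \code{pairedTests}.
#' @export
runValidationBattery <- function(series, conf = 0.95) {
  .checkSeries(series)
  raters <- sort(unique(series$rater))
  if (length(raters) < 2) stop("battery needs at least 2 raters")
  levels <- sort(unique(series$set_angle_deg))
  reps <- sort(unique(series$replicate))
  cnt <- table(series$rater, series$set_angle_deg, series$replicate)
  if (any(cnt != 1))
    stop("series must be balanced: one measurement per rater, level, replicate")

  desc <- seriesDescriptives(series)

  cell <- function(r, lev, rep)
    series$measured_angle_deg[series$rater == r &
                              series$set_angle_deg == lev &
                              series$replicate == rep]
  relRows <- lapply(reps, function(rp) {
    m <- sapply(raters, function(r) vapply(levels, cell, 0, r = r, rep = rp))
    icc <- iccAbsoluteAgreement(m)
    pe <- tryCatch(pearsonCorrelation(m[, 1], m[, 2]),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(replicate = rp, icc = icc@icc, ciLow = icc@ciLow,
               ciHigh = icc@ciHigh, iccP = icc@p,
               degenerate = icc@degenerate, pearsonR = pe$r, pearsonP = pe$p)
  })
  reliability <- do.call(rbind, relRows)

  mAll <- do.call(rbind, lapply(reps, function(rp)
    sapply(raters, function(r) vapply(levels, cell, 0, r = r, rep = rp))))
  iccPooled <- iccAbsoluteAgreement(mAll)
  pePooled <- tryCatch(pearsonCorrelation(mAll[, 1], mAll[, 2]),
                       error = function(e) list(r = NA_real_, p = NA_real_))
  reliabilityPooled <- data.frame(
    label = c("pooled (all level x replicate pairs)",
              "mean of per-replicate ICCs"),
    icc = c(iccPooled@icc, mean(reliability$icc)),
    ciLow = c(iccPooled@ciLow, NA), ciHigh = c(iccPooled@ciHigh, NA),
    iccP = c(iccPooled@p, NA),
    pearsonR = c(pePooled$r, mean(reliability$pearsonR)),
    pearsonP = c(pePooled$p, NA))

  ptRows <- lapply(levels, function(lev) {
    d <- vapply(reps, function(rp) cell(raters[1], lev, rp) -
                  cell(raters[2], lev, rp), 0)
    if (sd(d) == 0) {
      data.frame(set_angle_deg = lev, meanDiff = mean(d), sdDiff = 0,
                 ciLow = mean(d), ciHigh = mean(d), t = NA_real_,
                 df = length(d) - 1, p = NA_real_, agreementExact = TRUE)
    } else {
      tt <- pairedTTest(diff = d, conf = conf)
      data.frame(set_angle_deg = lev, meanDiff = tt@meanDiff,
                 sdDiff = tt@sdDiff, ciLow = tt@ciLow, ciHigh = tt@ciHigh,
                 t = tt@t, df = tt@df, p = tt@p, agreementExact = FALSE)
    }
  })
  pairedTests <- do.call(rbind, ptRows)

  structure(list(descriptives = desc, reliability = reliability,
                 reliabilityPooled = reliabilityPooled,
                 pairedTests = pairedTests),
            class = "neckValidationReport")
}

#' @export
print.neckValidationReport <- function(x, ...) {
  cat("Validation battery\n")
  cat(sprintf("  pooled ICC(A,1): %.3f\n", x$reliabilityPooled$icc[1]))
  cat(sprintf("  per-replicate ICC range: %.3f-%.3f\n",
              min(x$reliability$icc), max(x$reliability$icc)))
  cat(sprintf("  paired-test |mean diff| range: %.2f-%.2f deg\n",
              min(abs(x$pairedTests$meanDiff)),
              max(abs(x$pairedTests$meanDiff))))
  invisible(x)
}
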