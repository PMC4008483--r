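#' Blood flux from a PC-MRI velocity map
#'
#' Sums the velocity values within the vessel ROI and converts to
#' volumetric flux: `flux = sum(v_i) * pixelArea * 60` with velocities
#' in cm/s and pixel area in cm^2, giving ml/min.
#'
#' @param velocity 2-D numeric matrix of velocities (cm/s).
#' @param roi 2-D logical matrix of the vessel ROI, same shape.
#' @param pixelArea pixel area in cm^2.
#' @return flux in ml/min.
#' @export
computeFlux <- function(velocity, roi, pixelArea) {
  if (!identical(dim(velocity), dim(roi))) stop("ROI shape must match the velocity map")
  if (!any(roi)) stop("empty ROI")
  sum(velocity[roi]) * pixelArea * 60
}

#' Inter-session coefficient of variation of a flux pair
#'
#' The two-replicate reproducibility index
#' `CoV = 100 * |F1 - F2| / ((F1 + F2) / 2)` (percent). Note the
#' alternative convention SD-of-pair/mean differs by a factor sqrt(2);
#' this package uses absolute difference over the pair mean.
#'
#' @param f1,f2 the two session measurements (both > 0).
#' @return CoV in percent.
#' @seealso [cohortCoV()]
#' @export
intersessionCoV <- function(f1, f2) {
  if (any(c(f1, f2) <= 0)) stop("fluxes must be positive")
  100 * abs(f1 - f2) / ((f1 + f2) / 2)
}

#' @rdname intersessionCoV
#' @param pairs two-column matrix (or data.frame) of session-1 and
#'   session-2 fluxes, one row per artery.
#' @return `cohortCoV`: list with per-pair `cov`, and their `mean` and
#'   `sd` across arteries.
#' @export
cohortCoV <- function(pairs) {
  pairs <- as.matrix(pairs)
  cv <- intersessionCoV(pairs[, 1], pairs[, 2])
  list(cov = cv, mean = mean(cv), sd = stats::sd(cv))
}

#' Log-scale Bland-Altman agreement
#'
#' Differences `d_i = ln(a_i) - ln(b_i)` between paired positive
#' measurements; reports the mean bias, its sample SD, the 95% limits
#' of agreement `mean +- 1.96 * SD`, and the geometric mean ratio
#' `exp(mean(d))` (the multiplicative bias between the two methods).
#'
#' @param a,b paired positive measurement vectors (length >= 2).
#' @return an `AgreementReport` list: `n`, `meanLogDiff`, `sdLogDiff`,
#'   `limits` (lower, upper), `gmr`, and the per-pair `logDiffs`.
#' @export
blandAltmanLog <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (any(a <= 0) || any(b <= 0)) stop("measurements must be positive for the log transform")
  d <- log(a) - log(b)
  m <- mean(d); s <- stats::sd(d)
  out <- list(n = length(d), meanLogDiff = m, sdLogDiff = s,
              limits = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
              gmr = exp(m), logDiffs = d)
  class(out) <- "AgreementReport"
  out
}

#' @export
print.AgreementReport <- function(x, ...) {
  cat(sprintf("Bland-Altman (log scale), n = %d\n", x$n))
  cat(sprintf("  mean log-difference %.4f (GMR %.4f), SD %.4f\n",
              x$meanLogDiff, x$gmr, x$sdLogDiff))
  cat(sprintf("  95%% limits of agreement [%.4f, %.4f]\n",
              x$limits[1], x$limits[2]))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` on an r x c contingency
#' table, `df = (r - 1)(c - 1)`, upper-tail p, no continuity
#' correction.
#'
#' @param table integer matrix (>= 2 x 2) of non-negative counts with
#'   no zero row or column total.
#' @return list with `statistic`, `df`, `p`, and `expected` counts.
#' @export
chiSquareIndependence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column total: expected counts undefined")
  }
  ## the small-expected-count approximation caveat is inherent to the
  ## Pearson test on sparse tables; the statistic itself is exact
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Success-rate accounting of the application study
#'
#' From the subject counts of the three performance groups (all four
#' arteries positioned / exactly one failed / all failed), derives the
#' artery-level tally: `successes = 4 * nAll + 3 * nOneFailed` of
#' `4 * nSubjects` attempted, with artery- and subject-level success
#' rates in percent (one decimal).
#'
#' @param nAll subjects with all four arteries positioned.
#' @param nOneFailed subjects with exactly one artery failed.
#' @param nAllFailed subjects with no positioning output.
#' @return a `SuccessAccounting` list: `groups`, `subjects`,
#'   `arteriesAttempted`, `arteriesSuccessful`, `arteryRate`,
#'   `subjectRate` (percent, rounded to one decimal) and the unrounded
#'   `arteryRateExact`/`subjectRateExact`.
#' @export
successAccounting <- function(nAll, nOneFailed, nAllFailed) {
  if (any(c(nAll, nOneFailed, nAllFailed) < 0)) stop("counts must be >= 0")
  subjects <- as.integer(nAll + nOneFailed + nAllFailed)
  attempted <- 4L * subjects
  successes <- as.integer(4 * nAll + 3 * nOneFailed)
  arteryRate <- if (attempted > 0) 100 * successes / attempted else NA_real_
  subjectRate <- if (subjects > 0) 100 * nAll / subjects else NA_real_
  out <- list(groups = c(allSuccessful = nAll, oneArteryFailed = nOneFailed,
                         allFailed = nAllFailed),
              subjects = subjects, arteriesAttempted = attempted,
              arteriesSuccessful = successes,
              arteryRate = round(arteryRate, 1),
              subjectRate = round(subjectRate, 1),
              arteryRateExact = arteryRate, subjectRateExact = subjectRate)
  class(out) <- "SuccessAccounting"
  out
}

#' @export
print.SuccessAccounting <- function(x, ...) {
  cat(sprintf("SuccessAccounting: %d subjects (%d / %d / %d)\n",
              x$subjects, x$groups[1], x$groups[2], x$groups[3]))
  cat(sprintf("  arteries: %d of %d positioned (%.1f%%); subjects all-four: %.1f%%\n",
              x$arteriesSuccessful, x$arteriesAttempted, x$arteryRate,
              x$subjectRate))
  invisible(x)
}
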