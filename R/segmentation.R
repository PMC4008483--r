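## Global Otsu threshold on a fixed-bin histogram: maximizes
## between-class variance (equivalently minimizes intraclass variance).
.otsuThreshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot threshold a constant volume")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  between <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-levels])
  breaks[k + 1L]                      # threshold at the bin boundary
}

#' Otsu body mask
#'
#' Separates body (tissue + arteries) from air with Otsu's threshold on
#' a 256-bin histogram of the whole volume; the resulting "object
#' region" is where the artery-threshold statistics are computed.
#'
#' @param volume a [Volume3D] with at least two distinct intensities.
#' @return a [BinaryMask3D] of voxels above the Otsu threshold.
#' @seealso [adaptiveArteryThreshold()]
#' @export
otsuBodyMask <- function(volume) {
  stopifnot(is(volume, "Volume3D"))
  thr <- .otsuThreshold(as.vector(volume@data))
  BinaryMask3D(volume@data > thr, volume)
}

#' Adaptive artery threshold with the 60% z-coverage search
#'
#' Thresholds the angiogram at `T_j = mu_O + j * sigma_O` (mean and
#' population SD of the body-region intensities), searching j from
#' `jHigh` down to `jLow`. At each j the thresholded mask is handed to
#' the artery-identification stage; j is accepted as soon as all four
#' arteries are identified and each spans at least `lengthFraction` of
#' the slice range in z (slice extent `(z_max - z_min + 1) / N_z`). If
#' no j satisfies the rule the `jLow` mask is returned with status
#' `"accepted_at_lower_bound"`; whether the run can proceed is then
#' decided by the >= 3-artery rule downstream.
#'
#' @param volume a [Volume3D].
#' @param body the body [BinaryMask3D] from [otsuBodyMask()]; must be
#'   non-empty.
#' @param jHigh,jLow integer search bounds (default 5 down to 3).
#' @param lengthFraction minimum z-coverage fraction (default 0.6).
#' @param candidates number of largest connected objects to consider
#'   (default 8).
#' @return a `ThresholdSearchResult` list: `j`, `threshold`, `mask`
#'   ([BinaryMask3D]), `fractions` (per identified artery), `status`
#'   (`"accepted"` or `"accepted_at_lower_bound"`), `labeling` (the
#'   [labelArteries()] result at the accepted j), and `muO`/`sigmaO`.
#' @export
adaptiveArteryThreshold <- function(volume, body, jHigh = 5L, jLow = 3L,
                                    lengthFraction = 0.6, candidates = 8L) {
  stopifnot(is(volume, "Volume3D"), is(body, "BinaryMask3D"))
  if (!any(body@data)) stop("empty body mask")
  if (jHigh < jLow || jLow < 1) stop("need jHigh >= jLow >= 1")
  vals <- volume@data[body@data]
  muO <- mean(vals)
  sigmaO <- sqrt(mean((vals - muO)^2))    # population SD
  nz <- dim(volume)[3]
  result <- NULL
  for (j in seq(jHigh, jLow)) {
    thr <- muO + j * sigmaO
    mask <- BinaryMask3D(volume@data > thr, volume)
    objects <- connectedComponents(mask)
    cand <- selectCandidates(objects, k = candidates)
    sections <- middleSliceSections(cand, volume)
    labeling <- labelArteries(cand, sections, volume)
    found <- names(labeling$labels)[!vapply(labeling$labels, is.null, TRUE)]
    fractions <- vapply(labeling$labels[found], function(l) {
      zr <- l$object$zRange
      (zr[2] - zr[1] + 1) / nz
    }, numeric(1))
    result <- list(j = j, threshold = thr, mask = mask,
                   fractions = fractions, status = "accepted",
                   labeling = labeling, muO = muO, sigmaO = sigmaO)
    class(result) <- "ThresholdSearchResult"
    if (length(found) == 4L && all(fractions >= lengthFraction)) {
      return(result)
    }
  }
  result$status <- "accepted_at_lower_bound"
  result
}

#' @export
print.ThresholdSearchResult <- function(x, ...) {
  cat(sprintf("ThresholdSearchResult: j = %d, T = %.2f (%s)\n",
              x$j, x$threshold, x$status))
  if (length(x$fractions)) {
    cat("  z-coverage:",
        paste(sprintf("%s %.2f", names(x$fractions), x$fractions),
              collapse = ", "), "\n")
  }
  invisible(x)
}
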