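#' Build a VA derivative template from a profile population
#'
#' Profiles (each with annotated turning indices) are aligned on the
#' midpoints of their turning-index pairs, cropped to the common
#' support, and averaged pointwise. The template turning indices are
#' the rounded means of the aligned individual indices.
#'
#' @param profiles list of [DerivativeProfile] with `turns` annotated;
#'   all must share `dz` and `axis`.
#' @param P padding half-width in samples defining the rough region
#'   around the template turning points (default 10).
#' @param side "left" or "right" (stored on the template).
#' @return a [Template].
#' @seealso [generateProfilePopulation()], [crossCorrelate()]
#' @export
buildTemplate <- function(profiles, P = 10L, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  dz <- profiles[[1]]@dz
  axis <- profiles[[1]]@axis
  for (p in profiles) {
    if (abs(p@dz - dz) > 1e-9) stop("profiles have mismatched dz")
    if (p@axis != axis) stop("profiles have mismatched transverse axis")
    if (any(is.na(p@turns))) stop("profiles must have annotated turning indices")
  }
  mids <- vapply(profiles, function(p) floor(mean(p@turns)), 0)
  ## relative index = absolute - mid; common support across profiles
  lo <- max(vapply(seq_along(profiles),
                   function(i) 1 - mids[i], 0))
  hi <- min(vapply(seq_along(profiles),
                   function(i) length(profiles[[i]]@values) - mids[i], 0))
  if (hi - lo + 1 < 4) stop("profiles share too little support to average")
  rel <- lo:hi
  vals <- rowMeans(vapply(seq_along(profiles), function(i) {
    profiles[[i]]@values[rel + mids[i]]
  }, numeric(length(rel))))
  t1 <- round(mean(vapply(profiles, function(p) p@turns[1], 0) - mids)) - lo + 1
  t2 <- round(mean(vapply(profiles, function(p) p@turns[2], 0) - mids)) - lo + 1
  new("Template", values = vals, dz = dz, turnLower = as.integer(t1),
      turnUpper = as.integer(t2), padding = as.integer(P), side = side,
      axis = axis)
}

#' Match a subject profile against a template by cross-correlation
#'
#' Normalized cross-correlation (both signals zero-meaned and
#' unit-normed over the overlap) is evaluated at every integer offset m
#' (profile sample `i + m` paired with template sample `i`) whose
#' overlap covers at least half the template; the best offset is the
#' argmax (ties to the smallest m). Normalization makes the match
#' invariant to affine amplitude differences between subject and
#' template.
#'
#' @param profile a [DerivativeProfile]; must be at least half as long
#'   as the template.
#' @param template a [Template] with the same `dz` and axis.
#' @return list with `m` (best offset), `score` (R(m)), and the full
#'   `offsets`/`scores` vectors.
#' @export
crossCorrelate <- function(profile, template) {
  f <- profile@values; g <- template@values
  n <- length(f); ng <- length(g)
  if (n < ng / 2) stop("profile shorter than half the template")
  if (abs(profile@dz - template@dz) > 1e-9) stop("dz mismatch between profile and template")
  if (profile@axis != template@axis) stop("transverse-axis mismatch")
  minOv <- ceiling(ng / 2)
  ms <- (1 - ng + minOv - 1):(n - minOv)
  scores <- rep(NA_real_, length(ms))
  for (k in seq_along(ms)) {
    m <- ms[k]
    i1 <- max(1L, 1L - m); i2 <- min(ng, n - m)
    if (i2 - i1 + 1L < minOv) next
    a <- f[(i1:i2) + m]; b <- g[i1:i2]
    a <- a - mean(a); b <- b - mean(b)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) next
    scores[k] <- sum(a * b) / (na * nb)
  }
  if (all(is.na(scores))) stop("degenerate correlation: zero variance at every offset")
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  list(m = ms[best], score = scores[best], offsets = ms, scores = scores)
}

#' Rough turning-point region from a template match
#'
#' Pads the matched template turning indices by the template's padding
#' P: the region is `[turnLower + m - P, turnUpper + m + P]` clipped to
#' the profile range. If clipping leaves fewer than `3 * Lmin` samples
#' the artery fails with reason "turning region outside profile".
#'
#' @param profile a [DerivativeProfile].
#' @param template the matched [Template].
#' @param m best offset from [crossCorrelate()].
#' @param Lmin minimum samples per subregion (default 2).
#' @return list with `lo`, `hi` (1-based inclusive profile indices) and
#'   `status` ("ok"/"failed" + `reason`).
#' @export
roughRegion <- function(profile, template, m, Lmin = 2L) {
  n <- length(profile@values)
  lo <- as.integer(max(1, template@turnLower + m - template@padding))
  hi <- as.integer(min(n, template@turnUpper + m + template@padding))
  if (hi - lo + 1L < 3L * Lmin) {
    return(list(lo = lo, hi = hi, status = "failed",
                reason = "turning region outside profile"))
  }
  list(lo = lo, hi = hi, status = "ok")
}

#' Detect the two turning points by three-segment variance minimization
#'
#' Finds the pair (k1, k2) splitting the segment into three subregions
#' `[1..k1]`, `[k1+1..k2]`, `[k2+1..n]` such that the total
#' within-subregion sum of squared deviations V1 + V2 + V3 is minimal,
#' each subregion holding at least `Lmin` samples. Computed exactly in
#' O(n^2) using prefix sums; ties resolve to the lexicographically
#' smallest (k1, k2).
#'
#' @param segment numeric vector (profile samples within the rough
#'   region), length >= `3 * Lmin`.
#' @param Lmin minimum subregion length (default 2).
#' @param offset integer added to the returned indices to map them back
#'   to full-profile coordinates (default 0).
#' @return a [TurningPointPair] with `k1 < k2` (boundary indices: k1 is
#'   the last sample of subregion 1, k2 the last of subregion 2) and
#'   the minimized objective `vTotal`.
#' @export
detectTurningPoints <- function(segment, Lmin = 2L, offset = 0L) {
  x <- as.numeric(segment)
  n <- length(x)
  if (n < 3L * Lmin) stop("segment too short for three subregions")
  s1 <- cumsum(x); s2 <- cumsum(x^2)
  sse <- function(a, b) {        # sum of squared deviations over x[a..b]
    s <- s1[b] - ifelse(a > 1, s1[a - 1], 0)
    q <- s2[b] - ifelse(a > 1, s2[a - 1], 0)
    q - s^2 / (b - a + 1)
  }
  bestV <- Inf; bestK <- c(NA_integer_, NA_integer_)
  for (k1 in Lmin:(n - 2L * Lmin)) {
    k2s <- (k1 + Lmin):(n - Lmin)
    v <- sse(1L, k1) + sse(k1 + 1L, k2s) + sse(k2s + 1L, n)
    i <- which.min(v)
    if (v[i] < bestV) {
      bestV <- v[i]
      bestK <- c(k1, k2s[i])
    }
  }
  new("TurningPointPair", k1 = as.integer(bestK[1] + offset),
      k2 = as.integer(bestK[2] + offset), vTotal = max(0, bestV))
}

## interpolate a centerline point at height z (clamped to its z range)
.centerlineAt <- function(centerline, z) {
  pts <- coords(centerline)
  zr <- range(pts[, 3])
  z <- min(max(z, zr[1]), zr[2])
  unname(c(stats::approx(pts[, 3], pts[, 1], xout = z, ties = mean)$y,
           stats::approx(pts[, 3], pts[, 2], xout = z, ties = mean)$y,
           z))
}

## tangent by first principal direction of the points within +-window
## indices of the point nearest z; sign with positive F-H component
.tangentAt <- function(centerline, z, window = 5L) {
  pts <- coords(centerline)
  i0 <- which.min(abs(pts[, 3] - z))
  lo <- max(1L, i0 - window); hi <- min(nrow(pts), i0 + window)
  if (hi - lo + 1L < 3L) {      # shrink symmetrically, never below 3 points
    need <- 3L - (hi - lo + 1L)
    lo <- max(1L, lo - need); hi <- min(nrow(pts), hi + need)
    message("tangent window shrunk to available centerline extent")
  }
  pc <- stats::prcomp(pts[lo:hi, , drop = FALSE], center = TRUE)
  v <- unname(pc$rotation[, 1])
  if (v[3] < 0) v <- -v
  v / sqrt(sum(v^2))
}

## angulation (alpha about L-R, beta about A-P, gamma = 0) reproducing a
## unit normal: normal = (cos a sin b, sin a, cos a cos b)
.normalToAngulation <- function(n) {
  a <- asin(pmin(1, pmax(-1, n[2])))
  b <- atan2(n[1], n[3])
  c(a, b, 0) * 180 / pi
}

.volumeCenter <- function(volume) {
  origin(volume) + (dim(volume) - 1) * spacing(volume) / 2
}

.makeScanPlane <- function(center, tangent, volume) {
  n <- unname(tangent) / sqrt(sum(tangent^2))
  if (n[3] < 0) n <- -n
  center <- unname(center)
  new("ScanPlane", offcenter = center - .volumeCenter(volume),
      center = center, normal = n,
      angulation = unname(.normalToAngulation(n)))
}

#' Plan the VA scan plane from detected turning points
#'
#' The plane centre is the centerline point at the profile-index
#' midpoint `floor((k1 + k2) / 2)` of the two turning points (the
#' straight stretch between the C2 and C1 bends); the normal is the
#' local tangent, estimated as the first principal direction of the
#' centerline points within `window` points of the centre.
#'
#' @param centerline the VA [Centerline].
#' @param profile its [DerivativeProfile] (supplies the index-to-z map).
#' @param turns a [TurningPointPair] in full-profile coordinates.
#' @param window half-width (points) of the tangent neighbourhood.
#' @param volume the parent [Volume3D] (for the off-center reference).
#' @return a [ScanPlane].
#' @export
planVaPlane <- function(centerline, profile, turns, window = 5L, volume) {
  midIdx <- floor((turns@k1 + turns@k2) / 2)
  zStar <- profile@z0 + (midIdx - 1) * profile@dz
  centre <- .centerlineAt(centerline, zStar)
  tangent <- .tangentAt(centerline, zStar, window)
  .makeScanPlane(centre, tangent, volume)
}

#' Plan the ICA scan plane at the VA upper-turn level
#'
#' The ICA plane sits where the ICA crosses the horizontal plane
#' through the upper turning point of the same-side VA (the
#' foramen-magnum level); the normal is the local ICA tangent. If the
#' turn level lies outside the ICA centerline's z span the nearest
#' endpoint is used (with a message).
#'
#' @param centerline the ICA [Centerline].
#' @param upperTurn numeric(3) mm point of the VA upper turning point.
#' @param window tangent neighbourhood half-width (points).
#' @param volume the parent [Volume3D].
#' @return a [ScanPlane].
#' @export
planIcaPlane <- function(centerline, upperTurn, window = 5L, volume) {
  zStar <- upperTurn[3]
  zr <- range(coords(centerline)[, 3])
  if (zStar < zr[1] || zStar > zr[2]) {
    message("VA upper-turn level outside ICA centerline span; using nearest endpoint")
  }
  centre <- .centerlineAt(centerline, zStar)
  tangent <- .tangentAt(centerline, zStar, window)
  .makeScanPlane(centre, tangent, volume)
}
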