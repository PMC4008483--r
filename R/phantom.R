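#' Specification of a synthetic TOF-like vascular phantom
#'
#' Describes a neck-like volume containing four bright, near-vertical
#' tubular arteries over a dimmer tissue cylinder: two internal carotid
#' arteries (ICA) each with an external carotid (ECA) branch splitting
#' off above a common trunk, and two vertebral arteries (VA) each with
#' two smooth bends (the C2- and C1-level turns) at known heights.
#' Geometry is analytic, so ground-truth centerlines, turning points and
#' ideal scan planes are available exactly.
#'
#' Intensities follow the TOF contrast model: tissue voxels are
#' `tissueMean` plus Gaussian texture of SD `tissueSD`; artery voxels sit
#' `contrast` tissue SDs above the tissue mean, optionally tapering
#' linearly toward the top of the volume (mimicking flow-related signal
#' loss); independent Gaussian noise of SD `noiseSD` is added everywhere
#' and intensities are clamped at zero.
#'
#' @param dim integer(3) grid size; default 96 x 96 x 47 (47 axial slices).
#' @param spacing numeric(3) voxel size in mm; default 0.8 x 0.8 x 1.5.
#' @param icaRadius,vaRadius,ecaRadius tube radii in mm.
#' @param vaTurnHeights numeric(2) z (mm) of the lower and upper VA
#'   turning points; default 35% and 60% of the z extent.
#' @param vaBend numeric(2) displacement of the VA between its two turns,
#'   c(posterior, medial), mm.
#' @param icaLateral,icaAnterior,in-plane offsets (mm) of the ICAs from
#'   the volume centre; `icaCurve` amplitude (mm) of their gentle lateral
#'   bowing.
#' @param vaLateral,vaPosterior in-plane offsets (mm) of the VAs.
#' @param ecaBifurcation z (mm) at which the ECA leaves the carotid
#'   trunk; default 30% of the z extent (below the middle slice, so the
#'   carotid object shows two cross-sections there).
#' @param ecaSlope lateral mm per mm of height the ECA diverges by;
#'   `ecaLength` its height extent above the bifurcation (mm).
#' @param cornerHalfWidth half-width h (mm) of the C1 smoothing of each
#'   VA bend (slope ramps linearly over `[z_t - h, z_t + h]`).
#' @param tissueMean,tissueSD,contrast,noiseSD intensity model (a.u.).
#' @param taper fractional reduction of the artery-tissue contrast at
#'   the top of the volume (0 = constant-intensity arteries).
#' @param motionBlur logical; blur the final volume along A-P with a
#'   short kernel, emulating subject motion.
#' @param smallVAFactor scale factor applied to both VA radii (< 1
#'   emulates the hypoplastic-VA failure mode).
#' @param dropArteries character vector of labels among "LICA", "RICA",
#'   "LVA", "RVA" to omit entirely.
#' @return a `PhantomSpec` (validated list).
#' @seealso [generatePhantom()], [generateProfilePopulation()]
#' @export
phantomSpec <- function(dim = c(96L, 96L, 47L),
                        spacing = c(0.8, 0.8, 1.5),
                        icaRadius = 2.2, vaRadius = 1.4, ecaRadius = 1.5,
                        vaTurnHeights = NULL,
                        vaBend = c(posterior = 6, medial = 3),
                        icaLateral = 13, icaAnterior = 8, icaCurve = 1.5,
                        vaLateral = 7, vaPosterior = 10,
                        ecaBifurcation = NULL, ecaSlope = 0.55,
                        ecaLength = 16, cornerHalfWidth = 2.25,
                        tissueMean = 100, tissueSD = 20, contrast = 8,
                        noiseSD = 5, taper = 0, motionBlur = FALSE,
                        smallVAFactor = 1, dropArteries = character(0)) {
  zext <- (dim[3] - 1) * spacing[3]
  if (is.null(vaTurnHeights)) vaTurnHeights <- c(0.35, 0.60) * zext
  if (is.null(ecaBifurcation)) ecaBifurcation <- 0.30 * zext
  spec <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
               icaRadius = icaRadius, vaRadius = vaRadius,
               ecaRadius = ecaRadius,
               vaTurnHeights = as.numeric(vaTurnHeights),
               vaBend = unname(as.numeric(vaBend)),
               icaLateral = icaLateral, icaAnterior = icaAnterior,
               icaCurve = icaCurve, vaLateral = vaLateral,
               vaPosterior = vaPosterior, ecaBifurcation = ecaBifurcation,
               ecaSlope = ecaSlope, ecaLength = ecaLength,
               cornerHalfWidth = cornerHalfWidth, tissueMean = tissueMean,
               tissueSD = tissueSD, contrast = contrast, noiseSD = noiseSD,
               taper = taper, motionBlur = motionBlur,
               smallVAFactor = smallVAFactor,
               dropArteries = as.character(dropArteries))
  class(spec) <- "PhantomSpec"
  validatePhantomSpec(spec)
  spec
}

#' @rdname phantomSpec
#' @param spec a `PhantomSpec`.
#' @export
validatePhantomSpec <- function(spec) {
  zext <- (spec$dim[3] - 1) * spec$spacing[3]
  t <- spec$vaTurnHeights
  if (!(0 < t[1] && t[1] < t[2] && t[2] < zext)) {
    stop("VA turning heights must satisfy 0 < lower < upper < z extent")
  }
  if (spec$icaRadius <= 0 || spec$vaRadius <= 0 || spec$ecaRadius <= 0) {
    stop("tube radii must be positive")
  }
  if (spec$contrast <= 0) stop("contrast must be positive")
  if (spec$smallVAFactor <= 0) stop("smallVAFactor must be positive")
  bad <- setdiff(spec$dropArteries, c("LICA", "RICA", "LVA", "RVA"))
  if (length(bad)) stop("unknown artery labels in dropArteries: ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}

## C1 ramp: displacement reaching `total` between the two turn heights,
## slope ramping linearly over +-h around each turn (parabolic blends,
## straight in between). Returns displacement and slope at z.
.bendRamp <- function(z, zLower, zUpper, total, h) {
  sMax <- total / (zUpper - zLower)
  a1 <- zLower - h; a2 <- zLower + h
  b1 <- zUpper - h; b2 <- zUpper + h
  disp <- numeric(length(z))
  slope <- numeric(length(z))
  riseArea <- sMax * h                      # integral of the rising ramp
  i <- z >= a1 & z < a2
  slope[i] <- sMax * (z[i] - a1) / (2 * h)
  disp[i] <- sMax * (z[i] - a1)^2 / (4 * h)
  i <- z >= a2 & z < b1
  slope[i] <- sMax
  disp[i] <- riseArea + sMax * (z[i] - a2)
  i <- z >= b1 & z < b2
  u <- z[i] - b1
  slope[i] <- sMax * (b2 - z[i]) / (2 * h)
  disp[i] <- riseArea + sMax * (b1 - a2) + sMax * (u - u^2 / (4 * h))
  i <- z >= b2
  disp[i] <- sMax * (zUpper - zLower)
  list(disp = disp, slope = slope)
}

## Analytic artery curves. side: -1 left, +1 right. Each returns, for a
## vector of z, an n x 3 matrix of mm points (and slopes on request).
.vaCurve <- function(spec, side, z, turnHeights = spec$vaTurnHeights,
                     bend = spec$vaBend, withSlope = FALSE) {
  cx <- (spec$dim[1] - 1) * spec$spacing[1] / 2
  cy <- (spec$dim[2] - 1) * spec$spacing[2] / 2
  x0 <- cx + side * spec$vaLateral
  y0 <- cy + spec$vaPosterior - bend[1] / 2   # centred so both turns fit
  h <- spec$cornerHalfWidth
  py <- .bendRamp(z, turnHeights[1], turnHeights[2], bend[1], h)
  px <- .bendRamp(z, turnHeights[1], turnHeights[2], -side * bend[2], h)
  pts <- cbind(x0 + px$disp, y0 + py$disp, z)
  if (!withSlope) return(pts)
  list(points = pts, slope = cbind(px$slope, py$slope))
}

.icaCurve <- function(spec, side, z, withSlope = FALSE) {
  cx <- (spec$dim[1] - 1) * spec$spacing[1] / 2
  cy <- (spec$dim[2] - 1) * spec$spacing[2] / 2
  zext <- (spec$dim[3] - 1) * spec$spacing[3]
  x <- cx + side * (spec$icaLateral + spec$icaCurve * sin(pi * z / zext))
  pts <- cbind(x, rep(cy - spec$icaAnterior, length(z)), z)
  if (!withSlope) return(pts)
  dx <- side * spec$icaCurve * (pi / zext) * cos(pi * z / zext)
  list(points = pts, slope = cbind(dx, rep(0, length(z))))
}

.ecaCurve <- function(spec, side, z) {
  ica <- .icaCurve(spec, side, z)
  off <- side * spec$ecaSlope * pmax(0, z - spec$ecaBifurcation)
  cbind(ica[, 1] + off, ica[, 2], z)
}

## Rasterize a polyline (n x 3 mm) as a union of spheres of radius r.
## Returns sorted unique linear voxel indices.
.stampTube <- function(points, r, dim, spacing, origin) {
  nOff <- ceiling(r / spacing)
  offs <- as.matrix(expand.grid(-nOff[1]:nOff[1], -nOff[2]:nOff[2],
                                -nOff[3]:nOff[3]))
  n <- nrow(points); m <- nrow(offs)
  base <- round(sweep(sweep(points, 2, origin), 2, spacing, "/")) + 1
  idx <- base[rep(seq_len(n), each = m), , drop = FALSE] +
    offs[rep(seq_len(m), n), , drop = FALSE]
  ctr <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
  d2 <- rowSums((ctr - points[rep(seq_len(n), each = m), , drop = FALSE])^2)
  ok <- d2 < r^2 &
    idx[, 1] >= 1 & idx[, 1] <= dim[1] &
    idx[, 2] >= 1 & idx[, 2] <= dim[2] &
    idx[, 3] >= 1 & idx[, 3] <= dim[3]
  idx <- idx[ok, , drop = FALSE]
  lin <- idx[, 1] + dim[1] * (idx[, 2] - 1) + dim[1] * dim[2] * (idx[, 3] - 1)
  sort(unique(lin))
}

## Build a Centerline from ordered mm points (dedupes zero-length steps).
.makeCenterline <- function(label, pts) {
  dimnames(pts) <- NULL
  step <- c(TRUE, rowSums(diff(pts)^2) > 1e-12)
  pts <- pts[step, , drop = FALSE]
  al <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  new("Centerline", label = label, points = pts, arcLength = al)
}

#' Generate a synthetic angiogram phantom with ground truth
#'
#' Rasterizes the artery tubes of a [phantomSpec()] into an intensity
#' volume (tissue cylinder + bright tubes + noise) and returns the exact
#' ground truth of every downstream quantity: centerlines, VA turning
#' points, and ideal scan planes (centre at the mid-turn point / upper
#' turn level, normal along the true tangent).
#'
#' @param spec a `PhantomSpec` from [phantomSpec()].
#' @param seed integer; the run is reproducible bit-for-bit per seed.
#' @return a list with elements `volume` (a [Volume3D]) and `truth`, a
#'   `PhantomGroundTruth` list: `centerlines` (named [Centerline] list,
#'   incl. ECA branches), `vaTurns` (per VA a 2 x 3 matrix of mm turn
#'   points, lower then upper), `idealPlanes` (per artery a list with
#'   `center` and unit `normal`), `arteryVoxels` (per artery the linear
#'   indices of its tube support), `bodyVoxels` (tissue + artery
#'   support) and the `spec`.
#' @examples
#' ph <- generatePhantom(phantomSpec(), seed = 1)
#' ph$volume
#' @export
generatePhantom <- function(spec, seed = 1L) {
  validatePhantomSpec(spec)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)

  dm <- spec$dim; sp <- spec$spacing; orig <- c(0, 0, 0)
  zext <- (dm[3] - 1) * sp[3]
  zFine <- seq(0, zext, by = 0.25)
  zCl <- seq(0, zext, by = 0.5)

  sides <- c(LICA = -1, RICA = 1, LVA = -1, RVA = 1)
  present <- setdiff(names(sides), spec$dropArteries)

  centerlines <- list()
  arteryVoxels <- list()
  vaTurns <- list()
  idealPlanes <- list()
  vaR <- spec$vaRadius * spec$smallVAFactor

  for (lab in present) {
    s <- sides[[lab]]
    if (grepl("ICA", lab)) {
      pts <- .icaCurve(spec, s, zFine)
      vox <- .stampTube(pts, spec$icaRadius, dm, sp, orig)
      ## ECA branch belongs to the same connected object
      zEca <- zFine[zFine >= spec$ecaBifurcation &
                    zFine <= spec$ecaBifurcation + spec$ecaLength]
      ecaPts <- .ecaCurve(spec, s, zEca)
      vox <- sort(unique(c(vox, .stampTube(ecaPts, spec$ecaRadius,
                                           dm, sp, orig))))
      centerlines[[lab]] <- .makeCenterline(lab, .icaCurve(spec, s, zCl))
      ecaLab <- sub("ICA", "ECA", lab)
      centerlines[[ecaLab]] <- .makeCenterline(ecaLab,
                                               .ecaCurve(spec, s, zEca))
    } else {
      pts <- .vaCurve(spec, s, zFine)
      vox <- .stampTube(pts, vaR, dm, sp, orig)
      centerlines[[lab]] <- .makeCenterline(lab, .vaCurve(spec, s, zCl))
      tp <- .vaCurve(spec, s, spec$vaTurnHeights)
      vaTurns[[lab]] <- tp
      zMid <- mean(spec$vaTurnHeights)
      mid <- .vaCurve(spec, s, zMid, withSlope = TRUE)
      tangent <- c(mid$slope[1, ], 1)
      idealPlanes[[lab]] <- list(center = drop(mid$points),
                                 normal = tangent / sqrt(sum(tangent^2)))
    }
    arteryVoxels[[lab]] <- vox
  }
  ## ideal ICA planes use the same-side VA upper turn level (or the other
  ## side's if that VA is absent)
  for (lab in intersect(c("LICA", "RICA"), present)) {
    sameVA <- paste0(substr(lab, 1, 1), "VA")
    vaLab <- if (sameVA %in% names(vaTurns)) sameVA else
      setdiff(names(vaTurns), sameVA)[1]
    if (is.na(vaLab) || is.null(vaLab)) next
    zStar <- vaTurns[[vaLab]][2, 3]
    ic <- .icaCurve(spec, sides[[lab]], zStar, withSlope = TRUE)
    tangent <- c(ic$slope[1, ], 1)
    idealPlanes[[lab]] <- list(center = drop(ic$points),
                               normal = tangent / sqrt(sum(tangent^2)))
  }

  ## intensity model
  vol <- array(0, dm)
  cx <- (dm[1] - 1) * sp[1] / 2; cy <- (dm[2] - 1) * sp[2] / 2
  xs <- (seq_len(dm[1]) - 1) * sp[1]
  ys <- (seq_len(dm[2]) - 1) * sp[2]
  ell <- outer(((xs - cx) / (0.88 * cx))^2, ((ys - cy) / (0.78 * cy))^2, "+") <= 1
  tissue <- which(array(rep(ell, dm[3]), dm))
  vol[tissue] <- spec$tissueMean + stats::rnorm(length(tissue), 0, spec$tissueSD)

  allArtery <- sort(unique(unlist(arteryVoxels, use.names = FALSE)))
  if (length(allArtery)) {
    zOfLin <- ((allArtery - 1) %/% (dm[1] * dm[2])) * sp[3]
    margin <- spec$contrast * spec$tissueSD * (1 - spec$taper * zOfLin / zext)
    vol[allArtery] <- spec$tissueMean + margin
  }
  if (spec$noiseSD > 0) {
    vol <- vol + array(stats::rnorm(prod(dm), 0, spec$noiseSD), dm)
  }
  if (spec$motionBlur) {
    pad <- vol[, c(1, seq_len(dm[2]), dm[2]), ]
    vol <- (pad[, seq_len(dm[2]), ] + 2 * pad[, seq_len(dm[2]) + 1, ] +
            pad[, seq_len(dm[2]) + 2, ]) / 4
  }
  vol <- pmax(vol, 0)

  truth <- list(centerlines = centerlines, vaTurns = vaTurns,
                idealPlanes = idealPlanes, arteryVoxels = arteryVoxels,
                bodyVoxels = sort(unique(c(tissue, allArtery))),
                spec = spec)
  class(truth) <- "PhantomGroundTruth"
  list(volume = Volume3D(vol, spacing = sp, origin = orig), truth = truth)
}

#' Generate a population of VA derivative profiles with known turns
#'
#' Draws `n` vertebral-artery geometries from the phantom model with
#' jittered turn heights and bend displacements, and returns their
#' derivative profiles (computed from the analytic centerlines via
#' [derivativeProfile()]) annotated with the true turning sample
#' indices. Used to build matching templates ([buildTemplate()]).
#'
#' @param n number of profiles (>= 2).
#' @param spec a `PhantomSpec`; the population is centred on its VA
#'   geometry.
#' @param side "left" or "right".
#' @param jitter list with `turnSD` (mm SD of each turn height) and
#'   `bendSD` (mm SD of each bend displacement); zero gives identical
#'   profiles.
#' @param seed integer seed; the population is reproducible.
#' @return list of [DerivativeProfile] with `turns` annotated.
#' @export
generateProfilePopulation <- function(n, spec = phantomSpec(),
                                      side = c("left", "right"),
                                      jitter = list(turnSD = 2, bendSD = 1),
                                      seed = 1L) {
  if (n < 2) stop("need n >= 2 profiles")
  side <- match.arg(side)
  s <- if (side == "left") -1 else 1
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  zext <- (spec$dim[3] - 1) * spec$spacing[3]
  dz <- spec$spacing[3]
  zCl <- seq(0, zext, by = 0.5)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      th <- spec$vaTurnHeights + stats::rnorm(2, 0, jitter$turnSD)
      gap <- 4 * spec$cornerHalfWidth    # keep bends separated and inside
      if (th[1] > gap && th[2] < zext - gap && th[2] - th[1] > gap) break
    }
    bend <- pmax(1, spec$vaBend + stats::rnorm(2, 0, jitter$bendSD))
    pts <- .vaCurve(spec, s, zCl, turnHeights = th, bend = bend)
    cl <- .makeCenterline(paste0(toupper(substr(side, 1, 1)), "VA"), pts)
    pr <- derivativeProfile(cl, axis = "AP", dz = dz)
    turns <- as.integer(round((th - pr@z0) / dz) + 1)
    pr@turns <- turns
    out[[i]] <- pr
  }
  out
}

#' @export
print.PhantomGroundTruth <- function(x, ...) {
  cat("PhantomGroundTruth:", paste(names(x$centerlines), collapse = ", "), "\n")
  cat(sprintf("  VA turns at z = %.1f / %.1f mm; %d ideal planes\n",
              x$spec$vaTurnHeights[1], x$spec$vaTurnHeights[2],
              length(x$idealPlanes)))
  invisible(x)
}
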