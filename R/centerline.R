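## Weighted voxel-adjacency graph of an object (26-connectivity, edge
## weights = physical step length in mm).
.voxelGraph <- function(vox, dims, spacing) {
  n <- nrow(vox)
  mult <- cumprod(c(1, dims[-3]))
  lin <- as.vector(1 + (vox - 1) %*% mult)
  lookup <- integer(prod(dims))
  lookup[lin] <- seq_len(n)
  offs <- .offsets3d26()
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nbLin <- as.vector(1 + (nb[ok, , drop = FALSE] - 1) %*% mult)
    j <- lookup[nbLin]
    hit <- j > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
    w <- c(w, rep(sqrt(sum((offs[r, ] * spacing)^2)), sum(hit)))
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = n,
                          directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Extract an artery centerline as centres of geodesic level sets
#'
#' Computes geodesic distance from the inferior-most voxel of the
#' artery on the object's voxel-adjacency graph (26-connectivity,
#' physical edge lengths), bins voxels into distance level sets of
#' width `max(spacing)`, and takes the mm centroid of each level set as
#' a skeleton point. Voxels on side branches (e.g. the ECA limb of a
#' carotid object) are excluded beforehand: a voxel belongs to the
#' branch through the seed cross-section iff its distances to the
#' source and to the seed are consistent with lying on the source-seed
#' trunk or its continuation (`|d_seed - |d_src - d_src(seed)|| <=
#' 3 * max(spacing)`). The polyline is smoothed with a 3-point moving
#' average and constrained to non-decreasing z.
#'
#' @param object a connected object from [connectedComponents()].
#' @param seed its seed cross-section from [labelArteries()] /
#'   [middleSliceSections()].
#' @param volume the parent [Volume3D].
#' @param label artery label stored on the result.
#' @return a [Centerline] (inferior to superior).
#' @export
extractCenterline <- function(object, seed, volume, label = "artery") {
  vox <- object$voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("empty object")
  sp <- spacing(volume); o <- origin(volume); d <- dim(volume)
  g <- .voxelGraph(vox, d, sp)

  ## source: inferior-most voxel, nearest the in-slice centroid of the
  ## bottom layer (deterministic)
  zmin <- min(vox[, 3])
  bottom <- which(vox[, 3] == zmin)
  bc <- colMeans(vox[bottom, 1:2, drop = FALSE])
  src <- bottom[which.min((vox[bottom, 1] - bc[1])^2 +
                          (vox[bottom, 2] - bc[2])^2)]

  ## seed voxel: object voxel on the middle slice closest to the seed
  ## section centroid
  midZ <- floor(d[3] / 2) + 1L
  onMid <- which(vox[, 3] == midZ)
  if (length(onMid) == 0L) onMid <- seq_len(nrow(vox))
  seedMm <- seed$centroid
  vx <- o[1] + (vox[onMid, 1] - 1) * sp[1]
  vy <- o[2] + (vox[onMid, 2] - 1) * sp[2]
  seedIdx <- onMid[which.min((vx - seedMm[1])^2 + (vy - seedMm[2])^2)]

  dSrc <- as.vector(igraph::distances(g, v = src))
  dSeed <- as.vector(igraph::distances(g, v = seedIdx))
  S <- dSrc[seedIdx]
  tol <- 3 * max(sp)
  onBranch <- is.finite(dSrc) & is.finite(dSeed) &
    abs(dSeed - abs(dSrc - S)) <= tol

  width <- max(sp)
  bins <- floor(dSrc[onBranch] / width)
  mm <- cbind(o[1] + (vox[onBranch, 1] - 1) * sp[1],
              o[2] + (vox[onBranch, 2] - 1) * sp[2],
              o[3] + (vox[onBranch, 3] - 1) * sp[3])
  ub <- sort(unique(bins))
  if (length(ub) < 5L) stop("artery too short")
  pts <- t(vapply(ub, function(b) colMeans(mm[bins == b, , drop = FALSE]),
                  numeric(3)))

  ## 3-point moving average (endpoints kept)
  if (nrow(pts) >= 3L) {
    sm <- pts
    sm[2:(nrow(pts) - 1L), ] <- (pts[1:(nrow(pts) - 2L), ] +
                                 pts[2:(nrow(pts) - 1L), ] +
                                 pts[3:nrow(pts), ]) / 3
    pts <- sm
  }
  ## enforce upward travel
  keep <- pts[, 3] >= cummax(pts[, 3]) - 1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 5L) stop("artery too short")
  .makeCenterline(label, pts)
}

#' Derivative profile of a centerline
#'
#' Resamples the centerline's transverse coordinate (A-P by default) at
#' a uniform z step by linear interpolation and differentiates with
#' respect to z (central differences, one-sided at the endpoints). The
#' result is the dimensionless slope signal matched against a
#' [Template] to find the VA turning-point region.
#'
#' @param centerline a [Centerline] spanning at least `10 * dz` in z.
#' @param axis transverse axis, "AP" (default) or "LR".
#' @param dz sampling interval in mm; defaults to the median z step of
#'   the polyline.
#' @return a [DerivativeProfile].
#' @export
derivativeProfile <- function(centerline, axis = c("AP", "LR"), dz = NULL) {
  axis <- match.arg(axis)
  pts <- coords(centerline)
  z <- pts[, 3]
  if (is.null(dz)) dz <- stats::median(diff(z))
  if (max(z) - min(z) < 10 * dz) stop("centerline z-span too small")
  tcoord <- if (axis == "AP") pts[, 2] else pts[, 1]
  zi <- seq(min(z), max(z), by = dz)
  ti <- stats::approx(z, tcoord, xout = zi, ties = mean)$y
  n <- length(ti)
  f <- numeric(n)
  f[2:(n - 1)] <- (ti[3:n] - ti[1:(n - 2)]) / (2 * dz)
  f[1] <- (ti[2] - ti[1]) / dz
  f[n] <- (ti[n] - ti[n - 1]) / dz
  new("DerivativeProfile", values = f, dz = dz, z0 = zi[1], axis = axis)
}
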