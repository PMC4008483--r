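#' @import methods
NULL

#' Volume3D: a 3-D intensity volume with physical voxel geometry
#'
#' The sole imaging input of the positioning pipeline: a scalar intensity
#' grid (arbitrary units, e.g. a TOF angiogram) with voxel spacing in mm.
#' The axis convention is fixed throughout the package: the first array
#' dimension runs left to right (L->R), the second anterior to posterior
#' (A->P) and the third feet to head (F->H, inferior to superior). Voxel
#' indices are 1-based and a voxel's mm coordinate refers to its centre:
#' `mm = origin + (index - 1) * spacing`.
#'
#' @slot data 3-D numeric array of finite, non-negative intensities.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot origin numeric(3), mm coordinate of voxel (1,1,1).
#'
#' @seealso [readVolume()], [writeVolume()], [voxelToMm()]
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("Volume3D", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must have exactly 3 dimensions")
  if (any(dim(d) < 8L)) return("each dimension must have >= 8 voxels")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    return("spacing must be 3 strictly positive finite values (mm)")
  }
  if (length(object@origin) != 3L || any(!is.finite(object@origin))) {
    return("origin must be 3 finite mm values")
  }
  if (any(!is.finite(d))) return("intensities must all be finite")
  if (min(d) < 0) return("intensities must be non-negative")
  TRUE
})

#' BinaryMask3D: a boolean grid congruent with a parent volume
#'
#' Carries the voxel spacing and origin of the volume it was derived from,
#' so that mm geometry of mask voxels remains well defined.
#'
#' @slot data 3-D logical array, same shape as the parent volume.
#' @slot spacing numeric(3), parent voxel spacing in mm.
#' @slot origin numeric(3), parent origin in mm.
#' @export
setClass("BinaryMask3D",
  representation(data = "array", spacing = "numeric", origin = "numeric")
)

setValidity("BinaryMask3D", function(object) {
  if (length(dim(object@data)) != 3L) return("mask must be 3-D")
  if (!is.logical(object@data)) return("mask data must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    return("spacing must be 3 positive values")
  }
  TRUE
})

#' Centerline: an ordered artery skeleton polyline
#'
#' Points are ordered inferior to superior (increasing z) and expressed in
#' mm in the volume's (L->R, A->P, F->H) frame.
#'
#' @slot label character, artery label ("LICA", "RICA", "LVA", "RVA" or
#'   a free-form tag for synthetic curves).
#' @slot points numeric matrix, n x 3, ordered mm points.
#' @slot arcLength numeric(n), cumulative arc length in mm, strictly
#'   increasing, starting at 0.
#' @export
setClass("Centerline",
  representation(label = "character", points = "matrix",
                 arcLength = "numeric")
)

setValidity("Centerline", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be an n x 3 numeric matrix")
  if (nrow(p) < 5L) return("centerline needs >= 5 points")
  if (any(!is.finite(p))) return("points must be finite")
  al <- object@arcLength
  if (length(al) != nrow(p)) return("arcLength must match the number of points")
  if (any(diff(al) <= 0)) return("arc length must be strictly increasing")
  if (any(diff(p[, 3]) < 0)) return("z-coordinates must be non-decreasing")
  TRUE
})

#' DerivativeProfile: the 1-D transverse-slope signal of a vertebral artery
#'
#' The centerline's transverse coordinate (A-P by default) resampled at a
#' uniform z step and differentiated with respect to z; the signal matched
#' against a [Template] to locate the turning-point region.
#'
#' @slot values numeric, dimensionless slope samples d(transverse)/dz.
#' @slot dz numeric(1), uniform sampling interval in mm (> 0).
#' @slot z0 numeric(1), z position (mm) of the first sample.
#' @slot axis character, transverse axis used: "AP" or "LR".
#' @slot turns integer(2), optional annotated true turning sample indices
#'   (lower, upper); `NA` when unknown.
#' @export
setClass("DerivativeProfile",
  representation(values = "numeric", dz = "numeric", z0 = "numeric",
                 axis = "character", turns = "integer"),
  prototype(turns = c(NA_integer_, NA_integer_), axis = "AP")
)

setValidity("DerivativeProfile", function(object) {
  if (length(object@values) < 10L) return("profile needs >= 10 samples")
  if (any(!is.finite(object@values))) return("profile values must be finite")
  if (length(object@dz) != 1L || object@dz <= 0) return("dz must be a single positive mm value")
  if (!object@axis %in% c("AP", "LR")) return("axis must be 'AP' or 'LR'")
  if (length(object@turns) != 2L) return("turns must have length 2")
  t <- object@turns
  if (!any(is.na(t))) {
    if (t[1] >= t[2]) return("turns must satisfy lower < upper")
    if (t[1] < 1L || t[2] > length(object@values)) return("turns out of sample range")
  }
  TRUE
})

#' Template: a reference vertebral-artery derivative profile
#'
#' Built by averaging a population of subject profiles aligned on their
#' turning points ([buildTemplate()]). Matching a subject profile against
#' the template by normalized cross-correlation yields the rough region
#' within which the turning points are then detected exactly.
#'
#' @slot values numeric, template samples g(t).
#' @slot dz numeric(1), sampling interval in mm; must equal the profiles'.
#' @slot turnLower integer(1), sample index of the lower turning point.
#' @slot turnUpper integer(1), sample index of the upper turning point.
#' @slot padding integer(1), half-width P (samples) of the rough region
#'   padded around the template turning points.
#' @slot side character, "left" or "right".
#' @slot axis character, transverse axis, "AP" or "LR".
#' @export
setClass("Template",
  representation(values = "numeric", dz = "numeric", turnLower = "integer",
                 turnUpper = "integer", padding = "integer",
                 side = "character", axis = "character"),
  prototype(padding = 10L, axis = "AP")
)

setValidity("Template", function(object) {
  n <- length(object@values)
  if (n < 4L) return("template too short")
  if (object@dz <= 0) return("dz must be positive")
  if (object@turnLower >= object@turnUpper) return("turnLower must be < turnUpper")
  if (object@turnLower < 1L || object@turnUpper > n) return("turning indices out of range")
  if (object@padding < 0L) return("padding must be >= 0")
  if (!object@side %in% c("left", "right")) return("side must be 'left' or 'right'")
  if (!object@axis %in% c("AP", "LR")) return("axis must be 'AP' or 'LR'")
  TRUE
})

#' TurningPointPair: the two detected turning points on a profile
#'
#' Indices k1 < k2 into a [DerivativeProfile] minimizing the total
#' within-segment sum of squares of the three subregions, plus the
#' corresponding mm points on the centerline when available.
#'
#' @slot k1 integer(1), lower turning sample index (full-profile coords).
#' @slot k2 integer(1), upper turning sample index.
#' @slot vTotal numeric(1), minimized objective V1 + V2 + V3.
#' @slot points numeric matrix 2 x 3, mm points on the centerline at the
#'   turning z positions (may be NA for bare segment runs).
#' @export
setClass("TurningPointPair",
  representation(k1 = "integer", k2 = "integer", vTotal = "numeric",
                 points = "matrix"),
  prototype(points = matrix(NA_real_, 2, 3))
)

setValidity("TurningPointPair", function(object) {
  if (object@k1 >= object@k2) return("k1 must be < k2")
  if (!is.finite(object@vTotal) || object@vTotal < 0) return("vTotal must be finite and >= 0")
  if (!all(dim(object@points) == c(2L, 3L))) return("points must be 2 x 3")
  TRUE
})

#' ScanPlane: a PC-MRI slice prescription
#'
#' The six scanner parameters for one artery: the plane centre as three
#' off-center offsets (mm along L-R, A-P, F-H from the volume centre), and
#' the plane tilt as a unit normal plus the two angulation angles that
#' reproduce it. The documented rotation convention: starting from the
#' axial normal (0,0,1), rotate by alpha about the L-R axis (positive
#' alpha tilts the normal posteriorly), then by beta about the A-P axis
#' (positive beta tilts it to the right); gamma (in-plane) is identically
#' 0 because a plane carries no in-plane orientation. Explicitly,
#' `normal = (cos(alpha) sin(beta), sin(alpha), cos(alpha) cos(beta))`.
#'
#' @slot offcenter numeric(3), plane centre minus volume centre, mm.
#' @slot center numeric(3), absolute plane centre in volume mm coords.
#' @slot normal numeric(3), unit normal with positive F-H component.
#' @slot angulation numeric(3), (alpha, beta, gamma) in degrees, gamma = 0.
#' @export
setClass("ScanPlane",
  representation(offcenter = "numeric", center = "numeric",
                 normal = "numeric", angulation = "numeric")
)

setValidity("ScanPlane", function(object) {
  if (length(object@normal) != 3L) return("normal must have 3 components")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9) return("normal must be unit length")
  if (object@normal[3] <= 0) return("normal must have positive F-H component")
  if (length(object@offcenter) != 3L || length(object@center) != 3L) {
    return("offcenter and center must have 3 components")
  }
  if (length(object@angulation) != 3L) return("angulation must have 3 components")
  if (abs(object@angulation[3]) > 1e-12) return("gamma must be 0")
  a <- object@angulation[1] * pi / 180
  b <- object@angulation[2] * pi / 180
  n <- c(cos(a) * sin(b), sin(a), cos(a) * cos(b))
  if (max(abs(n - object@normal)) > 1e-9) {
    return("angulation does not reproduce the normal under the documented rotation")
  }
  TRUE
})

## ---- show methods ----

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume3D: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%.3g, %.3g, %.3g) mm\n",
              min(object@data), max(object@data),
              object@origin[1], object@origin[2], object@origin[3]))
  cat("  axes: x = L->R, y = A->P, z = F->H\n")
})

setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask3D: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline '%s': %d points, %.1f mm long, z in [%.1f, %.1f] mm\n",
              object@label, nrow(object@points), max(object@arcLength),
              object@points[1, 3], object@points[nrow(object@points), 3]))
})

setMethod("show", "DerivativeProfile", function(object) {
  cat(sprintf("DerivativeProfile (%s axis): %d samples at dz = %.3g mm from z = %.1f mm\n",
              object@axis, length(object@values), object@dz, object@z0))
  if (!any(is.na(object@turns))) {
    cat(sprintf("  annotated turns at samples %d, %d\n",
                object@turns[1], object@turns[2]))
  }
})

setMethod("show", "Template", function(object) {
  cat(sprintf("Template (%s VA, %s axis): %d samples at dz = %.3g mm, turns %d/%d, padding %d\n",
              object@side, object@axis, length(object@values), object@dz,
              object@turnLower, object@turnUpper, object@padding))
})

setMethod("show", "TurningPointPair", function(object) {
  cat(sprintf("TurningPointPair: k1 = %d, k2 = %d, V = %.4g\n",
              object@k1, object@k2, object@vTotal))
})

setMethod("show", "ScanPlane", function(object) {
  cat(sprintf("ScanPlane: off-center (%.2f, %.2f, %.2f) mm [RL, AP, FH]\n",
              object@offcenter[1], object@offcenter[2], object@offcenter[3]))
  cat(sprintf("  normal (%.4f, %.4f, %.4f), angulation (%.2f, %.2f, %.2f) deg\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@angulation[1], object@angulation[2], object@angulation[3]))
})
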