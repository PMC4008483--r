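#' Construct a Volume3D
#'
#' @param data 3-D numeric array of non-negative intensities; axis order
#'   x = L->R, y = A->P, z = F->H.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) mm coordinate of voxel (1,1,1); default (0,0,0).
#' @return a [Volume3D].
#' @examples
#' v <- Volume3D(array(1, dim = c(8, 8, 8)), spacing = c(0.8, 0.8, 1.5))
#' dim(v)
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask3D congruent with a parent volume
#'
#' @param data 3-D logical array.
#' @param parent the parent [Volume3D] whose geometry the mask inherits.
#' @return a [BinaryMask3D].
#' @export
BinaryMask3D <- function(data, parent) {
  stopifnot(is(parent, "Volume3D"))
  if (!identical(dim(data), dim(parent@data))) {
    stop("mask shape must match the parent volume")
  }
  new("BinaryMask3D", data = data, spacing = parent@spacing,
      origin = parent@origin)
}

## Decompose a NIfTI 4x4 xform (0-based ijk -> RAS mm) into an axis
## permutation + flips mapping the stored array onto the package
## convention (+x R, +y P, +z S). Errors if a voxel axis has no single
## dominant world axis.
.decomposeXform <- function(A) {
  R <- A[1:3, 1:3]
  worldAxis <- integer(3)
  sgn <- numeric(3)
  for (a in 1:3) {
    col <- R[, a]
    if (all(col == 0)) stop("degenerate qform/sform: zero column in rotation")
    w <- which.max(abs(col))
    worldAxis[a] <- w
    sgn[a] <- sign(col[w])
  }
  if (length(unique(worldAxis)) != 3L) {
    stop("ambiguous orientation: qform/sform does not map voxel axes ",
         "to distinct world axes")
  }
  list(worldAxis = worldAxis, sgn = sgn, scale = sqrt(colSums(R^2)))
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 image and remaps it to the package axis convention
#' (x = L->R, y = A->P, z = F->H) using the header xform: voxel axes are
#' permuted and flipped so that the first axis increases to the subject's
#' right, the second posteriorly and the third superiorly. Intensities
#' are unchanged; spacing is taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [Volume3D].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected 3-D volume, got ", length(dim(arr)), "-D image")
  }
  A <- unclass(RNifti::xform(img))
  dec <- .decomposeXform(A)
  ## desired sign of each world axis in package coords: +x(R), -y(A), +z(S)
  want <- c(1, -1, 1)
  perm <- order(dec$worldAxis)            # voxel axis feeding world axis w
  arr <- aperm(arr, perm)
  sgn <- dec$sgn[perm]
  sp <- dec$scale[perm]
  flip <- sgn != want
  d <- dim(arr)
  if (flip[1]) arr <- arr[d[1]:1, , , drop = FALSE]
  if (flip[2]) arr <- arr[, d[2]:1, , drop = FALSE]
  if (flip[3]) arr <- arr[, , d[3]:1, drop = FALSE]
  ## world coordinate of the new first voxel = original 0-based corner index
  idx0 <- numeric(3)
  idx0[perm[flip]] <- d[flip] - 1
  world <- (A %*% c(idx0, 1))[1:3]
  orig <- c(world[1], -world[2], world[3])
  Volume3D(arr, spacing = sp, origin = orig)
}

#' Write a Volume3D as NIfTI-1
#'
#' The file's qform/sform encode the package convention so that
#' `readVolume(writeVolume(v))` reproduces `v` exactly (data, spacing and
#' origin).
#'
#' @param volume a [Volume3D].
#' @param path output path (`.nii` or `.nii.gz`); its directory must exist.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume3D"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  sp <- volume@spacing
  o <- volume@origin
  aff <- rbind(cbind(diag(c(sp[1], -sp[2], sp[3])), c(o[1], -o[2], o[3])),
               c(0, 0, 0, 1))
  attr(aff, "code") <- 2L
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- sp
  img <- RNifti::`qform<-`(img, value = aff)
  img <- RNifti::`sform<-`(img, value = aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map voxel indices to mm coordinates and back
#'
#' Voxel indices are 1-based and refer to voxel centres:
#' `mm = origin + (index - 1) * spacing`.
#'
#' @param volume a [Volume3D] (or [BinaryMask3D]).
#' @param index integer(3) voxel index (1-based), within the grid.
#' @return `voxelToMm` numeric(3) mm coordinates; `mmToVoxel` numeric(3)
#'   fractional voxel index.
#' @export
voxelToMm <- function(volume, index) {
  d <- dim(volume)
  index <- as.numeric(index)
  if (length(index) != 3L || any(index < 1) || any(index > d)) {
    stop("index out of bounds for grid ", paste(d, collapse = "x"))
  }
  origin(volume) + (index - 1) * spacing(volume)
}

#' @rdname voxelToMm
#' @param mm numeric(3) mm coordinates.
#' @export
mmToVoxel <- function(volume, mm) {
  (as.numeric(mm) - origin(volume)) / spacing(volume) + 1
}
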