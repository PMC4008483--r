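#' Accessors for the package's core classes
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x a [Volume3D], [BinaryMask3D], [Centerline],
#'   [DerivativeProfile] or [Template] object, as appropriate.
#' @return `voxelData` the intensity/logical array; `spacing` and
#'   `origin` numeric(3) in mm; `coords` the n x 3 mm point matrix of a
#'   centerline; `arcLength` its cumulative arc length; `profileValues`
#'   the profile/template samples; `samplingInterval` the z step (mm);
#'   `turningIndices` the (lower, upper) turning sample indices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("turningIndices", function(x) standardGeneric("turningIndices"))

#' @rdname accessors
#' @export
setMethod("voxelData", "Volume3D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "BinaryMask3D", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("spacing", "Volume3D", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "BinaryMask3D", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("origin", "Volume3D", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("origin", "BinaryMask3D", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("coords", "Centerline", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("arcLength", "Centerline", function(x) x@arcLength)
#' @rdname accessors
#' @export
setMethod("profileValues", "DerivativeProfile", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("profileValues", "Template", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("samplingInterval", "DerivativeProfile", function(x) x@dz)
#' @rdname accessors
#' @export
setMethod("samplingInterval", "Template", function(x) x@dz)
#' @rdname accessors
#' @export
setMethod("turningIndices", "DerivativeProfile", function(x) x@turns)
#' @rdname accessors
#' @export
setMethod("turningIndices", "Template", function(x) c(x@turnLower, x@turnUpper))

#' @describeIn accessors grid dimensions of a volume
#' @export
setMethod("dim", "Volume3D", function(x) dim(x@data))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask3D", function(x) dim(x@data))
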