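#' @import methods
NULL

#' Accessor generics
#'
#' Accessors for the core data containers: [OCTVolume-class],
#' [EyePhantom-class], [AlignedPair-class] and [ChoroidMetrics-class].
#'
#' @param object An object of the documented class.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("fovMM", function(object) standardGeneric("fovMM"))

#' @rdname accessors
#' @export
setGeneric("voxelSizeMM", function(object) standardGeneric("voxelSizeMM"))

#' @rdname accessors
#' @export
setGeneric("deviceLabel", function(object) standardGeneric("deviceLabel"))

#' @rdname accessors
#' @export
setGeneric("signalStrength", function(object) standardGeneric("signalStrength"))

#' @rdname accessors
#' @export
setGeneric("referenceVolume", function(object) standardGeneric("referenceVolume"))

#' @rdname accessors
#' @export
setGeneric("degradedVolume", function(object) standardGeneric("degradedVolume"))

#' @rdname accessors
#' @export
setGeneric("inputVolume", function(object) standardGeneric("inputVolume"))

#' @rdname accessors
#' @export
setGeneric("ilmSurface", function(object) standardGeneric("ilmSurface"))

#' @rdname accessors
#' @export
setGeneric("rpeSurface", function(object) standardGeneric("rpeSurface"))

#' @rdname accessors
#' @export
setGeneric("csiSurface", function(object) standardGeneric("csiSurface"))

#' @rdname accessors
#' @export
setGeneric("lumenMask", function(object) standardGeneric("lumenMask"))

#' @rdname accessors
#' @export
setGeneric("foveaIndex", function(object) standardGeneric("foveaIndex"))

#' @rdname accessors
#' @export
setGeneric("pairShift", function(object) standardGeneric("pairShift"))

#' @rdname accessors
#' @export
setGeneric("pairProvenance", function(object) standardGeneric("pairProvenance"))
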