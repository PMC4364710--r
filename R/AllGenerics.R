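# Accessor generics. Slot access from user code should go through these.

#' Accessors for dualTRghost objects
#'
#' Read-only accessors for the S4 containers: sequence parameters
#' ([SequenceParams-class]), flip maps ([FlipMap-class]), image pairs
#' ([ImagePair-class]), k-space grids ([KSpaceGrid-class]) and assemblies
#' ([KSpaceAssembly-class]), and adaptation results
#' ([FlipAdaptation-class]).
#'
#' @param object the object to access.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tr1Ms", function(object) standardGeneric("tr1Ms"))
#' @rdname accessors
#' @export
setGeneric("tr2Ms", function(object) standardGeneric("tr2Ms"))
#' @rdname accessors
#' @export
setGeneric("teMs", function(object) standardGeneric("teMs"))
#' @rdname accessors
#' @export
setGeneric("t1Ms", function(object) standardGeneric("t1Ms"))
#' @rdname accessors
#' @export
setGeneric("t2starMs", function(object) standardGeneric("t2starMs"))
#' @rdname accessors
#' @export
setGeneric("m0", function(object) standardGeneric("m0"))

setMethod("tr1Ms", "SequenceParams", function(object) object@tr1)
setMethod("tr2Ms", "SequenceParams", function(object) object@tr2)
setMethod("teMs", "SequenceParams", function(object) object@te)
setMethod("t1Ms", "SequenceParams", function(object) object@t1)
setMethod("t2starMs", "SequenceParams", function(object) object@t2star)
setMethod("m0", "SequenceParams", function(object) object@m0)

#' @rdname accessors
#' @export
setGeneric("flipGrid", function(object) standardGeneric("flipGrid"))
#' @rdname accessors
#' @export
setGeneric("flipMask", function(object) standardGeneric("flipMask"))
#' @rdname accessors
#' @export
setGeneric("gridSize", function(object) standardGeneric("gridSize"))
#' @rdname accessors
#' @export
setGeneric("gradientAxis", function(object) standardGeneric("gradientAxis"))

setMethod("flipGrid", "FlipMap", function(object) object@grid)
setMethod("flipMask", "FlipMap", function(object) object@grid > 0)
setMethod("gridSize", "FlipMap", function(object) nrow(object@grid))
setMethod("gradientAxis", "FlipMap", function(object) object@gradientAxis)

#' @rdname accessors
#' @export
setGeneric("imgStrong", function(object) standardGeneric("imgStrong"))
#' @rdname accessors
#' @export
setGeneric("imgWeak", function(object) standardGeneric("imgWeak"))
#' @rdname accessors
#' @export
setGeneric("seqParams", function(object) standardGeneric("seqParams"))
#' @rdname accessors
#' @export
setGeneric("theta1Scale", function(object) standardGeneric("theta1Scale"))

setMethod("imgStrong", "ImagePair", function(object) object@imgStrong)
setMethod("imgWeak", "ImagePair", function(object) object@imgWeak)
setMethod("seqParams", "ImagePair", function(object) object@params)
setMethod("theta1Scale", "ImagePair", function(object) object@theta1Scale)

#' @rdname accessors
#' @export
setGeneric("kspaceData", function(object) standardGeneric("kspaceData"))
#' @rdname accessors
#' @export
setGeneric("weakLines", function(object) standardGeneric("weakLines"))
#' @rdname accessors
#' @export
setGeneric("assemblyScheme", function(object) standardGeneric("assemblyScheme"))
#' @rdname accessors
#' @export
setGeneric("correctionApplied", function(object) standardGeneric("correctionApplied"))

setMethod("kspaceData", "KSpaceGrid", function(object) object@data)
setMethod("kspaceData", "KSpaceAssembly", function(object) object@kspace@data)
setMethod("gridSize", "KSpaceGrid", function(object) nrow(object@data))
setMethod("gridSize", "KSpaceAssembly", function(object) nrow(object@kspace@data))
setMethod("weakLines", "KSpaceAssembly", function(object) object@weakLines)
setMethod("assemblyScheme", "KSpaceAssembly", function(object) object@scheme)
setMethod("correctionApplied", "KSpaceAssembly",
          function(object) object@correctionFactor)

#' @rdname accessors
#' @export
setGeneric("adaptedTheta1", function(object) standardGeneric("adaptedTheta1"))
#' @rdname accessors
#' @export
setGeneric("adaptScale", function(object) standardGeneric("adaptScale"))
#' @rdname accessors
#' @export
setGeneric("adaptResidual", function(object) standardGeneric("adaptResidual"))

setMethod("adaptedTheta1", "FlipAdaptation", function(object) object@theta1)
setMethod("adaptScale", "FlipAdaptation", function(object) object@scale)
setMethod("adaptResidual", "FlipAdaptation", function(object) object@residual)
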