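#' @name AcousticWindow-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the volume, surface, probe
#'   and planning classes. Each has an obvious method per class; none mutate.
#' @param x an AcousticWindow object
#' @return the slot value (see the individual class pages)
NULL

#' @rdname AcousticWindow-generics
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("axisDirections", function(x) standardGeneric("axisDirections"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("hounsfield", function(x) standardGeneric("hounsfield"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("basePoint", function(x) standardGeneric("basePoint"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("poseRotation", function(x) standardGeneric("poseRotation"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("axialDir", function(x) standardGeneric("axialDir"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("lateralDir", function(x) standardGeneric("lateralDir"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("elevationalDir", function(x) standardGeneric("elevationalDir"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("attenuation", function(x) standardGeneric("attenuation"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("tbar", function(x) standardGeneric("tbar"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("planScores", function(x) standardGeneric("planScores"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("planMethod", function(x) standardGeneric("planMethod"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("candidateIndices", function(x) standardGeneric("candidateIndices"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname AcousticWindow-generics
#' @export
setGeneric("reportAggregates", function(x) standardGeneric("reportAggregates"))
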