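# Accessors and show methods.

#' @rdname AcousticWindow-generics
setMethod("voxelSpacing", "CtVolume", function(x) x@spacing)
#' @rdname AcousticWindow-generics
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname AcousticWindow-generics
setMethod("voxelSpacing", "AttenuationField", function(x) x@spacing)

#' @rdname AcousticWindow-generics
setMethod("worldOrigin", "CtVolume", function(x) x@origin)
#' @rdname AcousticWindow-generics
setMethod("worldOrigin", "LabelVolume", function(x) x@origin)
#' @rdname AcousticWindow-generics
setMethod("worldOrigin", "AttenuationField", function(x) x@origin)

#' @rdname AcousticWindow-generics
setMethod("axisDirections", "CtVolume", function(x) x@axes)
#' @rdname AcousticWindow-generics
setMethod("axisDirections", "LabelVolume", function(x) x@axes)
#' @rdname AcousticWindow-generics
setMethod("axisDirections", "AttenuationField", function(x) x@axes)

#' @rdname AcousticWindow-generics
setMethod("gridDim", "CtVolume", function(x) dim(x@values))
#' @rdname AcousticWindow-generics
setMethod("gridDim", "LabelVolume", function(x) dim(x@labels))
#' @rdname AcousticWindow-generics
setMethod("gridDim", "AttenuationField", function(x) dim(x@mu))

#' @rdname AcousticWindow-generics
setMethod("hounsfield", "CtVolume", function(x) x@values)
#' @rdname AcousticWindow-generics
setMethod("labelArray", "LabelVolume", function(x) x@labels)
#' @rdname AcousticWindow-generics
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)
#' @rdname AcousticWindow-generics
setMethod("attenuation", "AttenuationField", function(x) x@mu)

#' @rdname AcousticWindow-generics
setMethod("surfacePoints", "SurfacePointCloud", function(x) x@points)
#' @rdname AcousticWindow-generics
setMethod("surfaceNormals", "SurfacePointCloud", function(x) x@normals)

#' @rdname AcousticWindow-generics
setMethod("basePoint", "ProbePose", function(x) x@basePoint)
#' @rdname AcousticWindow-generics
setMethod("poseRotation", "ProbePose", function(x) x@rotation)
#' @rdname AcousticWindow-generics
setMethod("axialDir", "ProbePose", function(x) as.numeric(x@rotation[, 3]))
#' @rdname AcousticWindow-generics
setMethod("lateralDir", "ProbePose", function(x) as.numeric(x@rotation[, 1]))
#' @rdname AcousticWindow-generics
setMethod("elevationalDir", "ProbePose",
          function(x) as.numeric(x@rotation[, 2]))

#' @rdname AcousticWindow-generics
setMethod("tbar", "TransmissionResult", function(x) x@mean)

#' @rdname AcousticWindow-generics
setMethod("poses", "PlanResult", function(x) x@poses)
#' @rdname AcousticWindow-generics
setMethod("planScores", "PlanResult", function(x) x@scores)
#' @rdname AcousticWindow-generics
setMethod("planMethod", "PlanResult", function(x) x@method)

#' @rdname AcousticWindow-generics
setMethod("candidateIndices", "CandidateSet", function(x) x@indices)

#' @rdname AcousticWindow-generics
setMethod("reportTable", "EvaluationReport", function(x) x@table)
#' @rdname AcousticWindow-generics
setMethod("reportAggregates", "EvaluationReport", function(x) x@aggregates)

setMethod("show", "CtVolume", function(object) {
    d <- dim(object@values)
    cat(sprintf("CtVolume: %d x %d x %d voxels, spacing %s mm\n",
                d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    cat(sprintf("  HU range [%.0f, %.0f], origin (%s) mm\n",
                min(object@values), max(object@values),
                paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@labels)
    ids <- sort(unique(as.integer(object@labels)))
    cat(sprintf("LabelVolume: %d x %d x %d voxels, labels {%s}\n",
                d[1], d[2], d[3], paste(ids, collapse = ", ")))
})

setMethod("show", "SurfacePointCloud", function(object) {
    cat(sprintf("SurfacePointCloud: %d points with outward normals\n",
                nrow(object@points)))
})

setMethod("show", "ProbeGeometry", function(object) {
    cat(sprintf(paste0("ProbeGeometry '%s': %d scan-lines, radius %.0f mm,",
                       " fov %.0f deg, depth %.0f mm\n"),
                object@name, object@nElements, object@arrayRadius,
                object@fovAngle, object@depth))
})

setMethod("show", "ProbePose", function(object) {
    cat(sprintf("ProbePose at (%s) mm, axial (%s)\n",
                paste(format(object@basePoint, digits = 4), collapse = ", "),
                paste(format(object@rotation[, 3], digits = 3),
                      collapse = ", ")))
})

setMethod("show", "AttenuationField", function(object) {
    d <- dim(object@mu)
    cat(sprintf("AttenuationField: %d x %d x %d, mu in [%.3g, %.3g]\n",
                d[1], d[2], d[3], min(object@mu), max(object@mu)))
})

setMethod("show", "TransmissionResult", function(object) {
    cat(sprintf("TransmissionResult: t-bar %.4f over %d scan-lines x %d samples\n",
                object@mean, ncol(object@perScanline),
                nrow(object@perScanline)))
})

setMethod("show", "CandidateSet", function(object) {
    cat(sprintf("CandidateSet: %d admissible surface points for target (%s)\n",
                length(object@indices),
                paste(format(object@target, digits = 4), collapse = ", ")))
})

setMethod("show", "PlanResult", function(object) {
    cat(sprintf("PlanResult (%s): %d pose(s), t-bar %s\n",
                object@method, length(object@poses),
                paste(format(object@scores, digits = 4), collapse = ", ")))
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    print(object@aggregates)
})

setMethod("show", "PlannerConfig", function(object) {
    cat(sprintf(paste0("PlannerConfig: alpha %.0f deg, roll grid %.0f deg, ",
                       "nu %.2g, ray step %s mm\n"),
                object@alphaDeg, object@angleGridStepDeg, object@nu,
                if (is.na(object@rayStepMm)) "auto" else
                    format(object@rayStepMm)))
})

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf(paste0("PhantomConfig: %s voxels at %s mm, %d rib(s), ",
                       "seed %d\n"),
                paste(object@volumeShape, collapse = "x"),
                paste(format(object@spacingMm, digits = 3), collapse = "x"),
                object@ribCount, object@seed))
})
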