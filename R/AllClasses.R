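# Central S4 classes. World coordinates are millimetres throughout; voxel
# indices are 0-based in the geometry maths (world position of voxel
# (0,0,0)'s centre is `origin`), and a voxel's world position refers to its
# centre.

.isUnit <- function(v, tol = 1e-6) abs(sqrt(sum(v^2)) - 1) < tol

.checkGridGeometry <- function(object) {
    msgs <- character()
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msgs <- c(msgs, "spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3 || any(!is.finite(object@origin)))
        msgs <- c(msgs, "origin must be 3 finite values")
    A <- object@axes
    if (!is.matrix(A) || any(dim(A) != c(3, 3)) || any(!is.finite(A))) {
        msgs <- c(msgs, "axes must be a finite 3x3 matrix")
    } else {
        if (max(abs(crossprod(A) - diag(3))) > 1e-6)
            msgs <- c(msgs, "axes must be orthonormal")
        else if (det(A) < 0)
            msgs <- c(msgs, "axes must be right-handed (det +1)")
    }
    msgs
}

#' @title Scalar CT volume with world geometry
#'
#' @description A 3D grid of CT intensities in Hounsfield units together with
#'   its world geometry: per-axis voxel size (mm), world position of the
#'   centre of voxel (0,0,0), and an orthonormal right-handed direction
#'   matrix whose columns are the world directions of the voxel axes.
#'
#' @slot values 3D numeric array of Hounsfield units
#' @slot spacing numeric(3), voxel size in mm, strictly positive
#' @slot origin numeric(3), world position (mm) of the first voxel centre
#' @slot axes 3x3 orthonormal right-handed direction matrix
#'
#' @seealso [ctVolume()], [readVolume()], [sampleTrilinear()]
#' @export
setClass("CtVolume",
    representation(values = "array", spacing = "numeric",
                   origin = "numeric", axes = "matrix"),
    validity = function(object) {
        msgs <- .checkGridGeometry(object)
        if (length(dim(object@values)) != 3)
            msgs <- c(msgs, "values must be a 3D array")
        if (anyNA(object@values) || any(!is.finite(object@values)))
            msgs <- c(msgs, "values must be finite")
        if (length(msgs)) msgs else TRUE
    })

#' Construct a CtVolume
#'
#' Intensities outside the plausible CT range \[-1024, 4000\] HU are clamped,
#' with a message reporting how many voxels were affected (guards the
#' attenuation mapping against reconstruction artifacts).
#'
#' @param values 3D numeric array of Hounsfield units
#' @param spacing numeric(3) voxel size in mm
#' @param origin numeric(3) world position of the first voxel centre (mm)
#' @param axes 3x3 orthonormal right-handed direction matrix
#' @return a [CtVolume-class] object
#' @examples
#' v <- ctVolume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1))
#' gridDim(v)
#' @export
ctVolume <- function(values, spacing = c(1, 1, 1), origin = spacing / 2,
                     axes = diag(3)) {
    values <- clampHounsfield(values)
    storage.mode(values) <- "double"
    new("CtVolume", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin), axes = axes)
}

# Clamp to the supported HU range, reporting the number of clamped voxels.
clampHounsfield <- function(values, lo = -1024, hi = 4000) {
    n <- sum(values < lo | values > hi, na.rm = TRUE)
    if (n > 0) {
        message(sprintf("clamped %d voxel(s) outside [%g, %g] HU", n, lo, hi))
        values[values < lo] <- lo
        values[values > hi] <- hi
    }
    values
}

#' @title Integer label volume co-registered with a CT volume
#'
#' @description Organ labels on the same grid as a [CtVolume-class]; label 0
#'   is reserved for background. `labelMap` maps label ids to semantic names,
#'   e.g. `c("1" = "liver")`.
#'
#' @slot labels 3D integer array
#' @slot labelMap named character vector, names are label ids
#' @slot spacing,origin,axes grid geometry, as for [CtVolume-class]
#' @seealso [labelVolume()]
#' @export
setClass("LabelVolume",
    representation(labels = "array", labelMap = "character",
                   spacing = "numeric", origin = "numeric", axes = "matrix"),
    validity = function(object) {
        msgs <- .checkGridGeometry(object)
        if (length(dim(object@labels)) != 3)
            msgs <- c(msgs, "labels must be a 3D array")
        if (!is.integer(object@labels))
            msgs <- c(msgs, "labels must be integer")
        if (length(object@labelMap) &&
            is.null(names(object@labelMap)))
            msgs <- c(msgs, "labelMap must be named by label id")
        if (length(msgs)) msgs else TRUE
    })

#' Construct a LabelVolume
#'
#' @param labels 3D integer array (0 = background)
#' @param spacing,origin,axes grid geometry, as for [ctVolume()]
#' @param labelMap named character vector mapping label ids to names
#' @return a [LabelVolume-class] object
#' @export
labelVolume <- function(labels, spacing = c(1, 1, 1), origin = spacing / 2,
                        axes = diag(3), labelMap = c("1" = "organ")) {
    storage.mode(labels) <- "integer"
    new("LabelVolume", labels = labels, labelMap = labelMap,
        spacing = as.numeric(spacing), origin = as.numeric(origin),
        axes = axes)
}

#' @title Body surface point cloud with outward normals
#'
#' @description The discretized patient surface: world points (mm) on the
#'   body boundary with outward unit normals, as extracted by
#'   [extractSurfacePoints()].
#'
#' @slot points n x 3 matrix of world positions (mm)
#' @slot normals n x 3 matrix of outward unit vectors
#' @slot sourceSpacing numeric(3), voxel spacing of the source grid (mm)
#' @export
setClass("SurfacePointCloud",
    representation(points = "matrix", normals = "matrix",
                   sourceSpacing = "numeric"),
    validity = function(object) {
        msgs <- character()
        if (ncol(object@points) != 3 || ncol(object@normals) != 3)
            msgs <- c(msgs, "points and normals must have 3 columns")
        if (nrow(object@points) != nrow(object@normals))
            msgs <- c(msgs, "one normal per point required")
        if (nrow(object@normals) > 0) {
            nn <- sqrt(rowSums(object@normals^2))
            if (any(abs(nn - 1) > 1e-6))
                msgs <- c(msgs, "normals must be unit length")
        }
        if (length(msgs)) msgs else TRUE
    })

#' @title Curvilinear probe geometry
#'
#' @description Description of a convex-array transducer sufficient for
#'   planning: number of modelled scan-lines, radius of curvature of the
#'   array, total angular aperture, and penetration depth. Defaults mirror a
#'   4DC7-3/40 abdominal probe driven at 140 mm depth, with 64 planning
#'   scan-lines subsampled from the physical 128 elements.
#'
#' @slot nElements integer, number of modelled scan-lines (>= 2)
#' @slot arrayRadius numeric, radius of curvature in mm
#' @slot fovAngle numeric, total angular aperture in degrees (0, 180)
#' @slot depth numeric, penetration depth d_y in mm
#' @slot name free-text identifier
#' @seealso [probeGeometry()], [scanlines()]
#' @export
setClass("ProbeGeometry",
    representation(nElements = "integer", arrayRadius = "numeric",
                   fovAngle = "numeric", depth = "numeric", name = "character"),
    validity = function(object) {
        msgs <- character()
        if (object@nElements < 2) msgs <- c(msgs, "nElements must be >= 2")
        if (object@arrayRadius <= 0) msgs <- c(msgs, "arrayRadius must be > 0")
        if (object@fovAngle <= 0 || object@fovAngle >= 180)
            msgs <- c(msgs, "fovAngle must be in (0, 180)")
        if (object@depth <= 0) msgs <- c(msgs, "depth must be > 0")
        if (length(msgs)) msgs else TRUE
    })

#' Construct a ProbeGeometry
#'
#' @param nElements number of modelled scan-lines
#' @param arrayRadius radius of curvature (mm)
#' @param fovAngle total angular aperture (degrees)
#' @param depth penetration depth (mm)
#' @param name free-text identifier
#' @return a [ProbeGeometry-class] object
#' @examples
#' probeGeometry()  # 4DC7-3/40-like defaults
#' @export
probeGeometry <- function(nElements = 64L, arrayRadius = 40, fovAngle = 70,
                          depth = 140, name = "4DC7-3/40") {
    new("ProbeGeometry", nElements = as.integer(nElements),
        arrayRadius = arrayRadius, fovAngle = fovAngle, depth = depth,
        name = name)
}

#' Read a ProbeGeometry from a YAML or JSON file
#'
#' Expects a block with fields `name`, `n_elements`, `array_radius_mm`,
#' `fov_deg`, `depth_mm`.
#'
#' @param path file path
#' @return a [ProbeGeometry-class] object
#' @export
readProbeGeometry <- function(path) {
    spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    probeGeometry(nElements = spec$n_elements,
                  arrayRadius = spec$array_radius_mm,
                  fovAngle = spec$fov_deg, depth = spec$depth_mm,
                  name = if (is.null(spec$name)) "probe" else spec$name)
}

#' @title Rigid probe pose
#'
#' @description A probe placement: rotation mapping the probe frame into the
#'   world and the base surface point. Probe-frame convention: +z axial (into
#'   tissue), +x lateral, +y elevational, so the world axes are
#'   `d_l = R (1,0,0)`, `d_e = R (0,1,0)`, `d_a = R (0,0,1)` with
#'   `d_e = d_a x d_l`.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1
#' @slot basePoint numeric(3), world position (mm) of the probe centre
#' @seealso [poseFrom()]
#' @export
setClass("ProbePose",
    representation(rotation = "matrix", basePoint = "numeric"),
    validity = function(object) {
        msgs <- character()
        R <- object@rotation
        if (any(dim(R) != c(3, 3)) ||
            max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
            msgs <- c(msgs, "rotation must be orthonormal with det +1")
        if (length(object@basePoint) != 3 || any(!is.finite(object@basePoint)))
            msgs <- c(msgs, "basePoint must be 3 finite values")
        if (length(msgs)) msgs else TRUE
    })

#' @title CT-derived acoustic attenuation proxy field
#'
#' @description The dimensionless attenuation proxy `mu = max(1 + HU/1000,
#'   epsilon)` on the CT grid. Only ratios of `mu` enter the transmission
#'   model; the positive floor `epsilon` makes air a near-total reflector and
#'   keeps the reflection-ratio denominator away from zero.
#'
#' @slot mu 3D numeric array, all values >= epsilon
#' @slot epsilon positive floor
#' @slot spacing,origin,axes grid geometry, as for [CtVolume-class]
#' @seealso [huToMu()]
#' @export
setClass("AttenuationField",
    representation(mu = "array", epsilon = "numeric",
                   spacing = "numeric", origin = "numeric", axes = "matrix"),
    validity = function(object) {
        msgs <- .checkGridGeometry(object)
        if (length(object@epsilon) != 1 || object@epsilon <= 0)
            msgs <- c(msgs, "epsilon must be a positive scalar")
        else if (any(object@mu < object@epsilon))
            msgs <- c(msgs, "all mu values must be >= epsilon")
        if (length(msgs)) msgs else TRUE
    })

#' @title Transmission evaluation of one probe pose
#'
#' @description Per-scan-line log-compressed cumulative transmission profiles
#'   and their mean, for one evaluated pose. Each profile starts at 1 on the
#'   skin and is non-increasing with depth.
#'
#' @slot perScanline (samples x scan-lines) matrix of log-compressed
#'   transmission, each column non-increasing in \[0, 1\]
#' @slot depths numeric vector of sample depths (mm)
#' @slot mean scalar mean transmission t-bar in \[0, 1\]
#' @slot pose the evaluated [ProbePose-class]
#' @seealso [meanTransmission()]
#' @export
setClass("TransmissionResult",
    representation(perScanline = "matrix", depths = "numeric",
                   mean = "numeric", pose = "ProbePose"),
    validity = function(object) {
        msgs <- character()
        ps <- object@perScanline
        if (any(ps < -1e-12) || any(ps > 1 + 1e-12))
            msgs <- c(msgs, "per-scanline transmission must lie in [0, 1]")
        if (nrow(ps) > 1 && any(diff(ps) > 1e-12))
            msgs <- c(msgs, "transmission must be non-increasing with depth")
        if (object@mean < -1e-12 || object@mean > 1 + 1e-12)
            msgs <- c(msgs, "mean must lie in [0, 1]")
        if (length(msgs)) msgs else TRUE
    })

#' @title Planner configuration
#'
#' @description Tunables of the pose planner: the coupling-angle limit
#'   `alphaDeg` between the probe axis and the inward surface normal (30
#'   degrees by default), the roll-angle grid step over \[0, 180) degrees,
#'   the ray-march step (NA = half the minimum voxel spacing), the
#'   log-compression factor `nu`, the deterministic tie-break rule, and the
#'   world reference "up" vector that keys roll angle zero.
#'
#' @slot alphaDeg maximum probe-to-normal angle, degrees, in (0, 90)
#' @slot angleGridStepDeg roll grid step in degrees; must divide 180
#' @slot rayStepMm ray-march step in mm, or NA for half the minimum spacing
#' @slot nu log-compression factor (> 0)
#' @slot tieBreak tie-break rule (lowest surface index, then smallest roll)
#' @slot referenceUp world unit vector keying roll zero
#' @seealso [plannerConfig()]
#' @export
setClass("PlannerConfig",
    representation(alphaDeg = "numeric", angleGridStepDeg = "numeric",
                   rayStepMm = "numeric", nu = "numeric",
                   tieBreak = "character", referenceUp = "numeric"),
    validity = function(object) {
        msgs <- character()
        if (object@alphaDeg <= 0 || object@alphaDeg >= 90)
            msgs <- c(msgs, "alphaDeg must be in (0, 90)")
        if (object@angleGridStepDeg <= 0 ||
            abs(180 / object@angleGridStepDeg -
                round(180 / object@angleGridStepDeg)) > 1e-9)
            msgs <- c(msgs, "angleGridStepDeg must divide 180")
        if (!is.na(object@rayStepMm) && object@rayStepMm <= 0)
            msgs <- c(msgs, "rayStepMm must be positive or NA")
        if (object@nu <= 0) msgs <- c(msgs, "nu must be > 0")
        if (!.isUnit(object@referenceUp))
            msgs <- c(msgs, "referenceUp must be a unit vector")
        if (length(msgs)) msgs else TRUE
    })

#' Construct a PlannerConfig
#'
#' @param alphaDeg coupling-angle limit in degrees
#' @param angleGridStepDeg roll grid step in degrees
#' @param rayStepMm ray-march step (mm); NA = half the minimum voxel spacing
#' @param nu log-compression factor
#' @param tieBreak tie-break rule identifier
#' @param referenceUp world unit vector keying roll zero
#' @return a [PlannerConfig-class] object
#' @export
plannerConfig <- function(alphaDeg = 30, angleGridStepDeg = 5,
                          rayStepMm = NA_real_, nu = 0.5,
                          tieBreak = "index-then-angle",
                          referenceUp = c(0, 0, 1)) {
    new("PlannerConfig", alphaDeg = alphaDeg,
        angleGridStepDeg = angleGridStepDeg, rayStepMm = rayStepMm, nu = nu,
        tieBreak = tieBreak, referenceUp = as.numeric(referenceUp))
}

#' @title Constraint-satisfying pose candidates for one target
#'
#' @description Indices into a [SurfacePointCloud-class] of the surface
#'   points admissible for a target: target distance below the penetration
#'   depth and probe-to-normal angle within the coupling limit.
#'
#' @slot indices integer indices into the surface cloud, ascending
#' @slot distance per-candidate target distance (mm)
#' @slot normalAngleDeg per-candidate probe-to-normal angle (degrees)
#' @slot target numeric(3) target point (mm)
#' @seealso [candidateSurfacePoints()]
#' @export
setClass("CandidateSet",
    representation(indices = "integer", distance = "numeric",
                   normalAngleDeg = "numeric", target = "numeric"),
    validity = function(object) {
        msgs <- character()
        n <- length(object@indices)
        if (length(object@distance) != n || length(object@normalAngleDeg) != n)
            msgs <- c(msgs, "distance and normalAngleDeg must match indices")
        if (n > 1 && any(diff(object@indices) <= 0))
            msgs <- c(msgs, "indices must be strictly ascending")
        if (length(msgs)) msgs else TRUE
    })

#' @title Planned probe pose(s) with scores and diagnostics
#'
#' @description Result of a planner run: one pose per target with its mean
#'   transmission score, the roll angle for transmission-optimised plans, the
#'   method tag ("ours" or "naive"), a per-candidate diagnostics table, the
#'   multi-view log-sum objective, and the targets the plan covers.
#'
#' @slot poses list of [ProbePose-class], one per target
#' @slot scores per-pose mean transmission in \[0, 1\]
#' @slot phiDeg per-pose roll angle in degrees (NA for the naive planner)
#' @slot method "ours" or "naive"
#' @slot candidates diagnostics data.frame (surface index, position, best
#'   roll, best score)
#' @slot objective multi-view sum of log scores (NA for single view)
#' @slot targets n x 3 matrix of target points (mm)
#' @export
setClass("PlanResult",
    representation(poses = "list", scores = "numeric", phiDeg = "numeric",
                   method = "character", candidates = "data.frame",
                   objective = "numeric", targets = "matrix"),
    validity = function(object) {
        msgs <- character()
        if (!object@method %in% c("ours", "naive"))
            msgs <- c(msgs, "method must be 'ours' or 'naive'")
        if (length(object@poses) != length(object@scores))
            msgs <- c(msgs, "one score per pose required")
        if (any(object@scores < -1e-12 | object@scores > 1 + 1e-12,
                na.rm = TRUE))
            msgs <- c(msgs, "scores must lie in [0, 1]")
        if (object@method == "ours" && length(object@poses) > 1) {
            bp <- vapply(object@poses, function(p) p@basePoint, numeric(3))
            if (max(abs(bp - bp[, 1])) > 1e-9)
                msgs <- c(msgs, "multi-view poses must share one base point")
        }
        if (length(msgs)) msgs else TRUE
    })

#' @title US-image-shaped CT slice at a probe pose
#'
#' @description CT intensities resampled on the image plane of a pose
#'   (spanned by the lateral and axial axes through the base point), with a
#'   boolean mask of the curvilinear fan region. Quality ratios are computed
#'   over in-fan pixels only.
#'
#' @slot pixels (lateral x axial) matrix of HU values
#' @slot fanMask logical matrix marking the curvilinear sector
#' @slot u,v pixel-centre coordinates along the lateral/axial axes (mm)
#' @slot pixelSpacing pixel size (mm)
#' @slot pose the sampled [ProbePose-class]
#' @slot nIn number of in-fan pixels
#' @seealso [extractPoseSlice()]
#' @export
setClass("PoseSlice",
    representation(pixels = "matrix", fanMask = "matrix", u = "numeric",
                   v = "numeric", pixelSpacing = "numeric",
                   pose = "ProbePose", nIn = "integer"),
    validity = function(object) {
        msgs <- character()
        if (!identical(dim(object@pixels), dim(object@fanMask)))
            msgs <- c(msgs, "pixels and fanMask must have identical shape")
        if (object@nIn != sum(object@fanMask))
            msgs <- c(msgs, "nIn must equal the count of in-fan pixels")
        if (object@nIn < 1) msgs <- c(msgs, "fan mask must be non-empty")
        if (length(msgs)) msgs else TRUE
    })

#' @title Acoustic-window quality report
#'
#' @description Per-pose non-soft-tissue ratio (r_ct) and organ-coverage
#'   ratio (r_seg) rows plus per-method mean and SD aggregates, as produced
#'   by [comparePlans()].
#'
#' @slot table per-pose data.frame (method, target_idx, r_ct, r_seg, t_bar,
#'   phi_deg)
#' @slot aggregates per-method data.frame of means and SDs
#' @slot beta1,beta2 soft-tissue HU window bounds
#' @export
setClass("EvaluationReport",
    representation(table = "data.frame", aggregates = "data.frame",
                   beta1 = "numeric", beta2 = "numeric"),
    validity = function(object) {
        msgs <- character()
        r <- c(object@table$r_ct, object@table$r_seg)
        if (length(r) && any(r < -1e-12 | r > 1 + 1e-12, na.rm = TRUE))
            msgs <- c(msgs, "ratios must lie in [0, 1]")
        if (object@beta1 >= object@beta2)
            msgs <- c(msgs, "beta1 must be below beta2")
        if (length(msgs)) msgs else TRUE
    })

#' @title Synthetic torso phantom configuration
#'
#' @description Parameters of the synthetic torso-like CT phantom: an
#'   elliptic soft-tissue body cylinder in air, bone-density rib arcs in
#'   axial planes with an intercostal gap (the acoustic windows), a labelled
#'   soft-tissue organ ellipsoid beneath the ribs, Gaussian HU noise, and a
#'   seed. The HU palette keeps body and organ inside the soft-tissue window
#'   \[-100, 150\] HU and ribs far above it.
#'
#' @slot volumeShape integer(3) voxels per axis
#' @slot spacingMm numeric(3) voxel size (mm)
#' @slot bodyHalfAxes numeric(2) half-axes of the body ellipse (mm), x and y
#' @slot bodyHu soft-tissue HU
#' @slot ribCount number of rib arcs
#' @slot ribRadius rib tube radius (mm)
#' @slot ribGap intercostal gap between rib surfaces (mm)
#' @slot ribArcDeg angular extent of each rib arc (degrees, centred on the
#'   anterior direction +y)
#' @slot ribHu rib HU (> 300)
#' @slot ribScale scale of the rib centreline ellipse relative to the body
#' @slot organCentre numeric(3) organ centre (mm)
#' @slot organHalfAxes numeric(3) organ half-axes (mm)
#' @slot organHu organ HU
#' @slot backgroundHu air HU
#' @slot noiseSigma Gaussian HU noise SD
#' @slot nTargets number of target points drawn inside the organ
#' @slot seed RNG seed
#' @seealso [phantomConfig()], [generatePhantom()]
#' @export
setClass("PhantomConfig",
    representation(volumeShape = "integer", spacingMm = "numeric",
                   bodyHalfAxes = "numeric", bodyHu = "numeric",
                   ribCount = "integer", ribRadius = "numeric",
                   ribGap = "numeric", ribArcDeg = "numeric",
                   ribHu = "numeric", ribScale = "numeric",
                   organCentre = "numeric", organHalfAxes = "numeric",
                   organHu = "numeric", backgroundHu = "numeric",
                   noiseSigma = "numeric", nTargets = "integer",
                   seed = "integer"),
    validity = function(object) {
        msgs <- character()
        if (object@ribGap <= 0) msgs <- c(msgs, "ribGap must be > 0")
        if (object@ribCount > 0 && object@ribHu <= 300)
            msgs <- c(msgs, "ribHu must exceed 300 HU")
        if (object@bodyHu < -100 || object@bodyHu > 150 ||
            object@organHu < -100 || object@organHu > 150)
            msgs <- c(msgs, "body and organ HU must lie in [-100, 150]")
        centre <- bodyCentre(object)
        rel <- (object@organCentre[1:2] - centre) / object@bodyHalfAxes
        reach <- sqrt(sum(rel^2)) +
            max(object@organHalfAxes[1:2] / object@bodyHalfAxes)
        if (reach >= 1)
            msgs <- c(msgs, "organ ellipsoid must lie strictly inside the body")
        zTop <- object@organCentre[3] + object@organHalfAxes[3]
        zBot <- object@organCentre[3] - object@organHalfAxes[3]
        if (zBot <= 0 ||
            zTop >= object@volumeShape[3] * object@spacingMm[3])
            msgs <- c(msgs, "organ must lie inside the volume along z")
        if (length(msgs)) msgs else TRUE
    })

# Body ellipse centre in world mm (x-y plane; the body is a full-height
# cylinder along z).
bodyCentre <- function(config) {
    ext <- config@volumeShape * config@spacingMm
    c(ext[1] / 2, ext[2] / 2 - 0.05 * ext[2])
}

#' Construct a PhantomConfig
#'
#' @param volumeShape voxels per axis
#' @param spacingMm voxel size (mm)
#' @param bodyHalfAxes half-axes of the body ellipse (mm)
#' @param bodyHu,organHu soft-tissue HU values
#' @param ribCount,ribRadius,ribGap,ribArcDeg,ribHu,ribScale rib arc
#'   parameters (count, tube radius mm, intercostal gap mm, angular extent
#'   deg, HU, centreline scale)
#' @param organCentre,organHalfAxes organ ellipsoid (mm); NULL places the
#'   organ beneath the anterior rib cage, centred laterally
#' @param backgroundHu air HU
#' @param noiseSigma Gaussian HU noise SD
#' @param nTargets number of organ target points
#' @param seed RNG seed
#' @return a [PhantomConfig-class] object
#' @examples
#' cfg <- phantomConfig()
#' @export
phantomConfig <- function(volumeShape = c(96L, 96L, 64L),
                          spacingMm = c(1.5, 1.5, 1.5),
                          bodyHalfAxes = c(60, 45), bodyHu = 40,
                          ribCount = 4L, ribRadius = 4, ribGap = 8,
                          ribArcDeg = 120, ribHu = 900, ribScale = 0.9,
                          organCentre = NULL, organHalfAxes = c(30, 16, 22),
                          organHu = 60, backgroundHu = -1000,
                          noiseSigma = 10, nTargets = 5L, seed = 42L) {
    ext <- volumeShape * spacingMm
    if (is.null(organCentre))
        organCentre <- c(ext[1] / 2, ext[2] / 2 - 0.05 * ext[2] +
                             0.45 * bodyHalfAxes[2], ext[3] / 2)
    new("PhantomConfig", volumeShape = as.integer(volumeShape),
        spacingMm = as.numeric(spacingMm),
        bodyHalfAxes = as.numeric(bodyHalfAxes), bodyHu = bodyHu,
        ribCount = as.integer(ribCount), ribRadius = ribRadius,
        ribGap = ribGap, ribArcDeg = ribArcDeg, ribHu = ribHu,
        ribScale = ribScale, organCentre = as.numeric(organCentre),
        organHalfAxes = as.numeric(organHalfAxes), organHu = organHu,
        backgroundHu = backgroundHu, noiseSigma = noiseSigma,
        nTargets = as.integer(nTargets), seed = as.integer(seed))
}
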