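# Pose planning. Candidates are the surface points satisfying the two hard
# constraints (target within penetration depth; probe axis within the
# coupling-angle cone of the inward surface normal). The transmission
# optimiser is an exhaustive two-stage search: per candidate the best roll
# angle on the grid over [0, 180) degrees, then the best candidate; ties
# break deterministically (lowest surface index, then smallest roll), so
# the result equals the joint argmax over the candidate x roll product set.

angleGrid <- function(config) {
    seq(0, pi - 1e-12, by = config@angleGridStepDeg * pi / 180)
}

resolveRayStep <- function(config, field) {
    if (is.na(config@rayStepMm)) defaultRayStep(field) else config@rayStepMm
}

#' Enumerate constraint-satisfying pose candidates
#'
#' Admits exactly the surface points with target distance below the probe
#' depth and probe-to-normal angle (between the axial direction and the
#' inward normal) at most `alphaDeg`; ordered by surface index.
#'
#' @param surface a [SurfacePointCloud-class]
#' @param target target point (world mm)
#' @param geometry a [ProbeGeometry-class]
#' @param config a [PlannerConfig-class]
#' @return a [CandidateSet-class]
#' @section Errors: if no surface point is admissible, an error of class
#'   `awNoWindowError` carrying nearest-miss diagnostics (`minDistance`,
#'   `minAngleDeg`) is signalled.
#' @export
candidateSurfacePoints <- function(surface, target, geometry,
                                   config = plannerConfig()) {
    stopifnot(nrow(surface@points) > 0)
    target <- as.numeric(target)
    d <- sweep(-surface@points, 2, target, "+")  # target - s
    dist <- sqrt(rowSums(d^2))
    da <- d / dist
    cosAngle <- rowSums(da * (-surface@normals))
    cosAngle <- pmin(1, pmax(-1, cosAngle))
    angleDeg <- acos(cosAngle) * 180 / pi
    ok <- dist < geometry@depth & angleDeg <= config@alphaDeg
    if (!any(ok)) {
        err <- structure(class = c("awNoWindowError", "error", "condition"),
                         list(message = sprintf(
                             paste0("no admissible acoustic window ",
                                    "(min distance %.1f mm, ",
                                    "min angle %.1f deg)"),
                             min(dist), min(angleDeg)),
                             call = sys.call(-1),
                             minDistance = min(dist),
                             minAngleDeg = min(angleDeg)))
        stop(err)
    }
    idx <- which(ok)
    new("CandidateSet", indices = as.integer(idx), distance = dist[idx],
        normalAngleDeg = angleDeg[idx], target = target)
}

# t-bar matrix (candidates x roll grid) through the compiled batch kernel.
candidateTbarMatrix <- function(field, geometry, candidates, surface,
                                config) {
    phis <- angleGrid(config)
    step <- resolveRayStep(config, field)
    nC <- length(candidates@indices)
    nA <- length(phis)
    rotations <- matrix(0, nC * nA, 9)
    bases <- matrix(0, nC * nA, 3)
    for (ci in seq_len(nC)) {
        s <- surface@points[candidates@indices[ci], ]
        for (ai in seq_len(nA)) {
            pose <- poseFrom(s, candidates@target, roll = phis[ai],
                             referenceUp = config@referenceUp)
            row <- (ci - 1) * nA + ai
            rotations[row, ] <- as.numeric(t(pose@rotation))
            bases[row, ] <- pose@basePoint
        }
    }
    tb <- tbarBatch(field, geometry, rotations, bases, step, config@nu)
    matrix(tb, nC, nA, byrow = TRUE)
}

candidateDiagnostics <- function(candidates, surface, tb, phis) {
    bestIdx <- apply(tb, 1, which.max)
    data.frame(index = candidates@indices,
               x = surface@points[candidates@indices, 1],
               y = surface@points[candidates@indices, 2],
               z = surface@points[candidates@indices, 3],
               distance = candidates@distance,
               normal_angle_deg = candidates@normalAngleDeg,
               phi_best_deg = phis[bestIdx] * 180 / pi,
               t_bar = tb[cbind(seq_along(bestIdx), bestIdx)])
}

#' Plan the best single-view pose
#'
#' Two-stage exhaustive maximisation of the mean transmission: per candidate
#' the best roll angle on the grid, then the best candidate; ties break by
#' lowest surface index, then smallest roll, making the result identical to
#' the joint argmax over the full candidate x roll product set.
#'
#' @param field an [AttenuationField-class]
#' @param surface a [SurfacePointCloud-class]
#' @param target target point (world mm)
#' @param geometry a [ProbeGeometry-class]
#' @param config a [PlannerConfig-class]
#' @return a [PlanResult-class] with one pose
#' @examples
#' ph <- generatePhantom(phantomConfig(volumeShape = c(48, 48, 32),
#'                                     spacingMm = c(3, 3, 3),
#'                                     bodyHalfAxes = c(55, 45),
#'                                     organHalfAxes = c(25, 13, 18),
#'                                     ribCount = 2L, noiseSigma = 0))
#' surf <- extractSurface(ph$ct, density = 0.02)
#' field <- huToMu(ph$ct)
#' plan <- planSingleView(field, surf, ph$targets[1, ], probeGeometry(),
#'                        plannerConfig(angleGridStepDeg = 30))
#' planScores(plan)
#' @export
planSingleView <- function(field, surface, target, geometry,
                           config = plannerConfig()) {
    candidates <- candidateSurfacePoints(surface, target, geometry, config)
    phis <- angleGrid(config)
    tb <- candidateTbarMatrix(field, geometry, candidates, surface, config)
    bestAngle <- apply(tb, 1, which.max)          # smallest phi on ties
    bestScore <- tb[cbind(seq_along(bestAngle), bestAngle)]
    win <- which.max(bestScore)                   # lowest index on ties
    phi <- phis[bestAngle[win]]
    pose <- poseFrom(surface@points[candidates@indices[win], ],
                     candidates@target, roll = phi,
                     referenceUp = config@referenceUp)
    new("PlanResult", poses = list(pose), scores = bestScore[win],
        phiDeg = phi * 180 / pi, method = "ours",
        candidates = candidateDiagnostics(candidates, surface, tb, phis),
        objective = NA_real_,
        targets = matrix(candidates@target, 1, 3))
}

#' Plan a multi-view trajectory with a shared base point
#'
#' Restricts the search to surface points admissible for every target (the
#' intersection of the per-target candidate sets). Given a base point the
#' product objective factorises over targets, so each target's roll is
#' optimised independently; the base point maximising the sum of log mean
#' transmissions is returned with one pose per target.
#'
#' @param field an [AttenuationField-class]
#' @param surface a [SurfacePointCloud-class]
#' @param targets n x 3 matrix of target points (world mm)
#' @param geometry a [ProbeGeometry-class]
#' @param config a [PlannerConfig-class]
#' @return a [PlanResult-class] with one pose per target, sharing a base
#'   point; `@objective` is the sum of log scores
#' @export
planMultiView <- function(field, surface, targets, geometry,
                          config = plannerConfig()) {
    if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3)
    nT <- nrow(targets)
    sets <- lapply(seq_len(nT), function(i)
        candidateSurfacePoints(surface, targets[i, ], geometry, config))
    common <- Reduce(intersect, lapply(sets, slot, "indices"))
    if (!length(common)) {
        counts <- vapply(sets, function(s) length(s@indices), integer(1))
        err <- structure(class = c("awNoWindowError", "error", "condition"),
                         list(message = paste0(
                             "no common acoustic window; per-target ",
                             "candidate counts: ",
                             paste(counts, collapse = ", ")),
                             call = sys.call(-1),
                             candidateCounts = counts))
        stop(err)
    }
    common <- sort(common)
    phis <- angleGrid(config)
    perTarget <- lapply(seq_len(nT), function(i) {
        keep <- match(common, sets[[i]]@indices)
        sub <- new("CandidateSet", indices = as.integer(common),
                   distance = sets[[i]]@distance[keep],
                   normalAngleDeg = sets[[i]]@normalAngleDeg[keep],
                   target = as.numeric(targets[i, ]))
        candidateTbarMatrix(field, geometry, sub, surface, config)
    })
    bestAngle <- lapply(perTarget, function(tb) apply(tb, 1, which.max))
    bestScore <- mapply(function(tb, ba) tb[cbind(seq_along(ba), ba)],
                        perTarget, bestAngle)
    bestScore <- matrix(bestScore, nrow = length(common))
    objective <- rowSums(log(bestScore))
    win <- which.max(objective)
    s <- surface@points[common[win], ]
    poseList <- lapply(seq_len(nT), function(i)
        poseFrom(s, targets[i, ], roll = phis[bestAngle[[i]][win]],
                 referenceUp = config@referenceUp))
    diag1 <- candidateDiagnostics(
        new("CandidateSet", indices = as.integer(common),
            distance = sets[[1]]@distance[match(common, sets[[1]]@indices)],
            normalAngleDeg =
                sets[[1]]@normalAngleDeg[match(common, sets[[1]]@indices)],
            target = as.numeric(targets[1, ])),
        surface, perTarget[[1]], phis)
    diag1$objective <- objective
    new("PlanResult", poses = poseList, scores = bestScore[win, ],
        phiDeg = vapply(seq_len(nT),
                        function(i) phis[bestAngle[[i]][win]] * 180 / pi,
                        numeric(1)),
        method = "ours", candidates = diag1, objective = objective[win],
        targets = targets)
}

#' Naive single-view baseline
#'
#' Picks the surface point nearest to the target as base point, aims the
#' axial axis at the target, and sets the lateral axis to
#' `(n x d_a)/|n x d_a|` from the surface normal `n` -- geometry only, no
#' transmission optimisation. The mean transmission of the resulting pose is
#' still reported for comparison when `field` is supplied.
#'
#' @param surface a [SurfacePointCloud-class]
#' @param target target point (world mm)
#' @param geometry a [ProbeGeometry-class]
#' @param field optional [AttenuationField-class] used only to score the pose
#' @param config a [PlannerConfig-class] (ray step, nu, reference up)
#' @return a [PlanResult-class] with method "naive"
#' @export
planNaiveSingle <- function(surface, target, geometry, field = NULL,
                            config = plannerConfig()) {
    stopifnot(nrow(surface@points) > 0)
    target <- as.numeric(target)
    d <- sweep(-surface@points, 2, target, "+")
    dist <- sqrt(rowSums(d^2))
    win <- which.min(dist)
    s <- surface@points[win, ]
    da <- unitVector(target - s)
    n <- surface@normals[win, ]
    cr <- crossProduct(n, da)
    if (vecNorm(cr) < 1e-8) {
        message("surface normal parallel to the axial axis; ",
                "using the reference-up construction")
        pose <- poseFrom(s, target, roll = 0,
                         referenceUp = config@referenceUp)
    } else {
        dl <- unitVector(cr)
        de <- crossProduct(da, dl)
        pose <- new("ProbePose",
                    rotation = cbind(dl, de, da, deparse.level = 0),
                    basePoint = s)
    }
    score <- if (is.null(field)) NA_real_ else scorePose(field, geometry,
                                                         pose, config)
    new("PlanResult", poses = list(pose), scores = score,
        phiDeg = NA_real_, method = "naive",
        candidates = data.frame(index = win, x = s[1], y = s[2], z = s[3],
                                distance = dist[win]),
        objective = NA_real_, targets = matrix(target, 1, 3))
}

scorePose <- function(field, geometry, pose, config) {
    step <- resolveRayStep(config, field)
    tbarBatch(field, geometry, matrix(as.numeric(t(pose@rotation)), 1),
              matrix(pose@basePoint, 1), step, config@nu)
}

#' Naive multi-view baseline
#'
#' Per target, base point and axial axis as in [planNaiveSingle()]; the
#' elevational axis is the normalised rejection of the trajectory direction
#' `d_T` from the axial axis (aiming at parallel image planes), and the
#' lateral axis completes the right-handed frame.
#'
#' @param surface a [SurfacePointCloud-class]
#' @param targets n x 3 matrix of target points (world mm)
#' @param geometry a [ProbeGeometry-class]
#' @param trajectoryDir unit trajectory direction `d_T`; default the
#'   normalised first-to-last target direction
#' @param field optional [AttenuationField-class] used only to score poses
#' @param config a [PlannerConfig-class]
#' @return a [PlanResult-class] with method "naive", one pose per target
#' @export
planNaiveMulti <- function(surface, targets, geometry, trajectoryDir = NULL,
                           field = NULL, config = plannerConfig()) {
    if (is.null(dim(targets))) targets <- matrix(targets, ncol = 3)
    nT <- nrow(targets)
    if (is.null(trajectoryDir))
        trajectoryDir <- unitVector(targets[nT, ] - targets[1, ])
    dT <- as.numeric(trajectoryDir)
    stopifnot(abs(vecNorm(dT) - 1) < 1e-6)
    poseList <- vector("list", nT)
    idxs <- integer(nT)
    for (i in seq_len(nT)) {
        target <- as.numeric(targets[i, ])
        d <- sweep(-surface@points, 2, target, "+")
        dist <- sqrt(rowSums(d^2))
        win <- which.min(dist)
        s <- surface@points[win, ]
        da <- unitVector(target - s)
        rej <- vectorRejection(dT, da)
        if (vecNorm(rej) < 1e-8)
            stop("trajectory direction parallel to the axial axis of ",
                 "target ", i)
        de <- unitVector(rej)
        dl <- crossProduct(de, da)
        poseList[[i]] <- new("ProbePose",
                             rotation = cbind(dl, de, da,
                                              deparse.level = 0),
                             basePoint = s)
        idxs[i] <- win
    }
    scores <- if (is.null(field)) rep(NA_real_, nT)
    else vapply(poseList, function(p) scorePose(field, geometry, p, config),
                numeric(1))
    new("PlanResult", poses = poseList, scores = scores,
        phiDeg = rep(NA_real_, nT), method = "naive",
        candidates = data.frame(index = idxs,
                                x = surface@points[idxs, 1],
                                y = surface@points[idxs, 2],
                                z = surface@points[idxs, 3]),
        objective = NA_real_, targets = targets)
}

#' Write a plan as JSON (+ candidate diagnostics CSV)
#'
#' One record per target: base point, row-major rotation, roll angle, score
#' and method. The candidates table goes to a sibling CSV when requested.
#'
#' @param plan a [PlanResult-class]
#' @param path output JSON path
#' @param candidatesCsv optional path for the diagnostics CSV
#' @return the JSON path, invisibly
#' @export
writePlanJson <- function(plan, path, candidatesCsv = NULL) {
    recs <- lapply(seq_along(plan@poses), function(i) {
        p <- plan@poses[[i]]
        list(method = plan@method, target_idx = i,
             target = as.numeric(plan@targets[i, ]),
             base_point = as.numeric(p@basePoint),
             rotation = as.numeric(t(p@rotation)),
             phi_deg = plan@phiDeg[i], t_bar = plan@scores[i])
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    if (!is.null(candidatesCsv))
        write.csv(plan@candidates, candidatesCsv, row.names = FALSE)
    invisible(path)
}

#' Read a plan JSON back into PlanResult objects
#'
#' Returns one single-pose [PlanResult-class] per record, named by method.
#'
#' @param path JSON path written by [writePlanJson()]
#' @return named list of [PlanResult-class] objects
#' @export
readPlanJson <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    out <- lapply(recs, function(r) {
        pose <- new("ProbePose",
                    rotation = matrix(unlist(r$rotation), 3, 3,
                                      byrow = TRUE),
                    basePoint = unlist(r$base_point))
        num1 <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
        res <- new("PlanResult", poses = list(pose), scores = num1(r$t_bar),
                   phiDeg = num1(r$phi_deg), method = r$method,
                   candidates = data.frame(), objective = NA_real_,
                   targets = matrix(unlist(r$target), 1, 3))
        if (!is.null(r$target_idx))
            attr(res, "targetIdx") <- as.integer(r$target_idx)
        res
    })
    names(out) <- vapply(recs, `[[`, character(1), "method")
    out
}
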