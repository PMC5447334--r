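# Acoustic-window quality on CT: resample the US-image-shaped slice at a
# pose and score it with the non-soft-tissue ratio (fraction of in-fan
# pixels outside the soft-tissue HU window [beta1, beta2]) and the
# organ-coverage ratio (fraction of in-fan pixels inside the organ label).
# Both ratios run over the curvilinear fan region only: the US image of a
# convex probe is the fan, and rectangle background would dilute them.

#' Extract the US-image-shaped CT slice at a pose
#'
#' The image plane passes through the base point and is spanned by the
#' lateral and axial axes; pixel (u, v) maps to `base + u d_l + v d_a` with
#' v in \[0, depth\]. CT values are sampled trilinearly (outside the grid is
#' air); the fan mask marks pixels inside the curvilinear sector given by
#' the array radius and aperture.
#'
#' @param volume a [CtVolume-class]
#' @param pose a [ProbePose-class]
#' @param geometry a [ProbeGeometry-class]
#' @param pixelSpacing pixel size in mm; default the minimum CT voxel
#'   spacing (avoids aliasing thin ribs)
#' @return a [PoseSlice-class]
#' @export
extractPoseSlice <- function(volume, pose, geometry, pixelSpacing = NULL) {
    if (is.null(pixelSpacing)) pixelSpacing <- min(volume@spacing)
    r <- geometry@arrayRadius
    half <- geometry@fovAngle / 2 * pi / 180
    uMax <- (r + geometry@depth) * sin(half)
    u <- seq(-uMax, uMax, by = pixelSpacing)
    v <- seq(0, geometry@depth, by = pixelSpacing)
    grid <- expand.grid(u = u, v = v)
    dl <- pose@rotation[, 1]
    da <- pose@rotation[, 3]
    pts <- outer(grid$u, dl) + outer(grid$v, da)
    pts <- sweep(pts, 2, pose@basePoint, "+")
    hu <- sampleVolume(volume, pts, outside = -1024, mode = 1L)
    mask <- fanSectorMask(grid$u, grid$v, geometry)
    new("PoseSlice", pixels = matrix(hu, length(u), length(v)),
        fanMask = matrix(mask, length(u), length(v)),
        u = u, v = v, pixelSpacing = pixelSpacing, pose = pose,
        nIn = as.integer(sum(mask)))
}

# In-plane sector test: polar coordinates about the centre of curvature at
# (u, v) = (0, -arrayRadius); inside iff the radius lies within
# [arrayRadius, arrayRadius + depth] and the angle within the aperture.
fanSectorMask <- function(u, v, geometry) {
    r <- geometry@arrayRadius
    half <- geometry@fovAngle / 2 * pi / 180
    rad <- sqrt(u^2 + (v + r)^2)
    ang <- atan2(u, v + r)
    rad >= r & rad <= r + geometry@depth & abs(ang) <= half
}

#' Non-soft-tissue ratio of a pose slice
#'
#' Fraction of in-fan pixels whose HU lies outside the soft-tissue window
#' (below `beta1` or above `beta2`): bone and air-filled areas that impair
#' ultrasound transmission. Lower is better.
#'
#' @param slice a [PoseSlice-class]
#' @param beta1 lower soft-tissue bound (default -100 HU)
#' @param beta2 upper soft-tissue bound (default 150 HU)
#' @return scalar in \[0, 1\]
#' @export
ratioNonSoftTissue <- function(slice, beta1 = -100, beta2 = 150) {
    if (beta1 >= beta2) stop("beta1 must be below beta2")
    if (slice@nIn < 1) stop("empty fan region")
    hu <- slice@pixels[slice@fanMask]
    mean(hu < beta1 | hu > beta2)
}

#' Organ-coverage ratio of a pose slice
#'
#' Fraction of in-fan pixels whose (nearest-neighbour sampled) label equals
#' the organ id: how much anatomical context of the target organ the image
#' provides. Higher is better.
#'
#' @param slice a [PoseSlice-class]
#' @param labels a [LabelVolume-class]
#' @param organLabel integer organ label id (default 1)
#' @return scalar in \[0, 1\]
#' @export
ratioSegmentation <- function(slice, labels, organLabel = 1L) {
    if (!as.character(organLabel) %in% names(labels@labelMap))
        stop("label id ", organLabel, " not present in the label map")
    grid <- expand.grid(u = slice@u, v = slice@v)
    dl <- slice@pose@rotation[, 1]
    da <- slice@pose@rotation[, 3]
    pts <- outer(grid$u, dl) + outer(grid$v, da)
    pts <- sweep(pts, 2, slice@pose@basePoint, "+")
    lab <- sampleVolume(labels, pts, outside = 0, mode = 0L)
    mean(lab[as.logical(slice@fanMask)] == organLabel)
}

#' Compare plans on slice-based quality metrics
#'
#' For every pose of every plan, extracts the pose slice and computes the
#' non-soft-tissue ratio and the organ-coverage ratio; aggregates mean and
#' SD per method (SD is 0 for a single pose).
#'
#' @param volume a [CtVolume-class]
#' @param labels a [LabelVolume-class] on the same grid
#' @param plans list of [PlanResult-class] objects
#' @param geometry a [ProbeGeometry-class]
#' @param beta1,beta2 soft-tissue HU window (defaults -100, 150)
#' @param pixelSpacing slice pixel size (mm); default minimum CT spacing
#' @param organLabel organ label id
#' @return an [EvaluationReport-class]
#' @export
comparePlans <- function(volume, labels, plans, geometry, beta1 = -100,
                         beta2 = 150, pixelSpacing = NULL, organLabel = 1L) {
    stopifnot(length(plans) >= 1)
    if (is(plans, "PlanResult")) plans <- list(plans)
    rows <- list()
    for (plan in plans) {
        planIdx <- attr(plan, "targetIdx")
        for (i in seq_along(plan@poses)) {
            slice <- extractPoseSlice(volume, plan@poses[[i]], geometry,
                                      pixelSpacing)
            rows[[length(rows) + 1]] <- data.frame(
                method = plan@method,
                target_idx = if (is.null(planIdx)) i else planIdx,
                r_ct = ratioNonSoftTissue(slice, beta1, beta2),
                r_seg = ratioSegmentation(slice, labels, organLabel),
                t_bar = plan@scores[i], phi_deg = plan@phiDeg[i])
        }
    }
    tab <- do.call(rbind, rows)
    sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
    agg <- do.call(rbind, lapply(split(tab, tab$method), function(g)
        data.frame(method = g$method[1],
                   r_ct_mean = mean(g$r_ct), r_ct_sd = sd0(g$r_ct),
                   r_seg_mean = mean(g$r_seg), r_seg_sd = sd0(g$r_seg),
                   t_bar_mean = mean(g$t_bar), n = nrow(g))))
    rownames(agg) <- NULL
    new("EvaluationReport", table = tab, aggregates = agg,
        beta1 = beta1, beta2 = beta2)
}

#' Write an evaluation report as CSV and JSON
#'
#' The per-pose table goes to `<stem>.csv`, the per-method aggregates to
#' `<stem>_summary.json`.
#'
#' @param report an [EvaluationReport-class]
#' @param stem output path stem (without extension)
#' @return character vector of the two paths, invisibly
#' @export
writeReport <- function(report, stem) {
    csv <- paste0(stem, ".csv")
    js <- paste0(stem, "_summary.json")
    write.csv(report@table, csv, row.names = FALSE)
    agg <- split(report@aggregates, report@aggregates$method)
    out <- lapply(agg, function(g)
        list(r_ct_mean = g$r_ct_mean, r_ct_sd = g$r_ct_sd,
             r_seg_mean = g$r_seg_mean, r_seg_sd = g$r_seg_sd,
             t_bar_mean = g$t_bar_mean, n = g$n))
    jsonlite::write_json(out, js, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    invisible(c(csv, js))
}
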