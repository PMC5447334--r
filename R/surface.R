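# Surface extraction: threshold the CT, keep the largest connected
# component, close one-voxel skin holes, then place surface points at the
# 0.5 iso-level of the Gaussian-smoothed mask with normals from the
# smoothed-mask gradient (sign-fixed outward), and subsample to a requested
# areal density by grid binning in volume-local coordinates (local binning
# keeps the extraction equivariant under rigid translation of the volume).

#' Extract the body mask from a CT volume
#'
#' Binarises at `thresholdHu`, keeps the largest 6-connected component and
#' applies a one-voxel morphological closing to remove skin holes.
#'
#' @param volume a [CtVolume-class]
#' @param thresholdHu air/tissue threshold (default -300 HU)
#' @return a logical 3D array
#' @seealso [extractSurfacePoints()], [extractSurface()]
#' @export
extractBodyMask <- function(volume, thresholdHu = -300) {
    mask <- volume@values > thresholdHu
    if (!any(mask))
        stop("no body found at threshold ", thresholdHu, " HU")
    lab <- labelComponentsCpp(as.logical(mask), dim(mask))
    counts <- tabulate(lab[lab > 0L])
    keep <- which.max(counts)
    binaryClose6(array(lab == keep, dim(mask)))
}

#' Extract surface points with outward normals
#'
#' Boundary voxels of the mask are projected onto the 0.5 iso-level of the
#' Gaussian-smoothed (sigma = 1 voxel) mask along their normals; normals are
#' the negated gradient of the smoothed mask (pointing away from the
#' interior). Points are subsampled approximately uniformly to `density`
#' points per mm^2 by grid binning at pitch `sqrt(1/density)`.
#'
#' @param mask logical 3D array, as from [extractBodyMask()]
#' @param volume the source [CtVolume-class] (provides the geometry)
#' @param density target point density, points per mm^2 (default 0.25)
#' @return a [SurfacePointCloud-class]
#' @export
extractSurfacePoints <- function(mask, volume, density = 0.25) {
    if (sum(mask) <= 1)
        stop("degenerate mask: surface extraction needs more than one voxel")
    sp <- volume@spacing
    smoothed <- gaussianSmooth3d(mask * 1, sigmaVox = 1)
    boundary <- mask & !binaryErode6(mask)
    idx <- which(boundary)
    d <- dim(mask)
    i0 <- cbind((idx - 1) %% d[1],
                ((idx - 1) %/% d[1]) %% d[2],
                (idx - 1) %/% (d[1] * d[2]))
    # central-difference gradient of the smoothed mask (voxel units)
    grad <- vapply(1:3, function(axis) {
        g <- (shiftArray(smoothed, axis, -1, fill = NA) -
                  shiftArray(smoothed, axis, 1, fill = NA)) / 2
        g[idx]
    }, numeric(length(idx)))
    # to world: directions * per-axis mm scaling, then outward = -gradient
    gw <- -(grad %*% diag(1 / sp)) %*% t(volume@axes)
    gn <- sqrt(rowSums(gw^2))
    ok <- gn > 1e-9
    i0 <- i0[ok, , drop = FALSE]
    gw <- gw[ok, , drop = FALSE] / gn[ok]
    pts <- voxelToWorld(i0, sp, volume@origin, volume@axes)
    pts <- projectToIsoLevel(pts, gw, smoothed, volume)
    # density subsampling: one point per (pitch mm)^3 bin of local coords
    pitch <- sqrt(1 / density)
    localPts <- sweep(pts, 2, volume@origin, "-") %*% volume@axes
    key <- paste(floor(localPts[, 1] / pitch),
                 floor(localPts[, 2] / pitch),
                 floor(localPts[, 3] / pitch))
    keep <- !duplicated(key)
    new("SurfacePointCloud", points = pts[keep, , drop = FALSE],
        normals = gw[keep, , drop = FALSE], sourceSpacing = sp)
}

# Slide each point along its outward normal to the 0.5 level of the
# smoothed mask (sub-voxel surface localisation); points without a bracketed
# crossing within +/- 1.5 voxels stay at the voxel centre.
projectToIsoLevel <- function(pts, normals, smoothed, volume) {
    h <- min(volume@spacing)
    offsets <- seq(-1.5, 1.5, by = 0.25) * h
    n <- nrow(pts)
    field <- new("CtVolume", values = smoothed, spacing = volume@spacing,
                 origin = volume@origin, axes = volume@axes)
    vals <- matrix(0, n, length(offsets))
    for (j in seq_along(offsets))
        vals[, j] <- sampleVolume(field, pts + offsets[j] * normals,
                                  outside = 0, mode = 1L)
    f <- vals - 0.5
    best <- rep(NA_real_, n)
    for (j in seq_len(length(offsets) - 1)) {
        crossing <- f[, j] >= 0 & f[, j + 1] < 0
        tj <- offsets[j] + (offsets[j + 1] - offsets[j]) *
            f[, j] / (f[, j] - f[, j + 1])
        upd <- crossing & (is.na(best) | abs(tj) < abs(best))
        best[upd] <- tj[upd]
    }
    shift <- ifelse(is.na(best), 0, best)
    pts + shift * normals
}

#' One-call surface extraction
#'
#' Convenience wrapper: [extractBodyMask()] then [extractSurfacePoints()].
#'
#' @inheritParams extractBodyMask
#' @inheritParams extractSurfacePoints
#' @return a [SurfacePointCloud-class]
#' @export
extractSurface <- function(volume, thresholdHu = -300, density = 0.25) {
    extractSurfacePoints(extractBodyMask(volume, thresholdHu), volume,
                         density = density)
}

#' Export a surface cloud as ASCII PLY
#'
#' Writes points, normals and an optional per-vertex scalar (as property
#' `quality`) for inspection in standard mesh viewers.
#'
#' @param surface a [SurfacePointCloud-class]
#' @param path output path
#' @param scalar optional numeric vector, one value per point
#' @return the path, invisibly
#' @export
writeSurfacePly <- function(surface, path, scalar = NULL) {
    p <- surface@points
    n <- surface@normals
    props <- c("x", "y", "z", "nx", "ny", "nz")
    cols <- cbind(p, n)
    if (!is.null(scalar)) {
        stopifnot(length(scalar) == nrow(p))
        props <- c(props, "quality")
        cols <- cbind(cols, scalar)
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(p)),
                 paste("property float", props),
                 "end_header"), con)
    write.table(format(cols, trim = TRUE, digits = 9), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    invisible(path)
}
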