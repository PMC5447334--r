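# Acoustic transmission model. CT Hounsfield units map affinely to a
# dimensionless attenuation proxy mu = max(1 + HU/1000, epsilon) (water -> 1,
# bone ~ 2, air -> the floor). Along a ray the fraction of intensity
# transmitted past the first K samples is exp(-sum r_k^2) with per-step
# reflection ratio r_k = |mu_{k+1} - mu_k| / (mu_k + mu_{k+1}); ratios are
# summed without a step-length factor so that one sharp interface
# contributes exactly r^2 regardless of sampling rate, recovering the
# single-interface coefficient 1 - r^2 to O(r^4). Rays sample mu at the
# nearest voxel (piecewise-constant media stay step-size invariant; see the
# methods vignette). A log compression log(1 + nu t)/log(1 + nu) mimics the
# dynamic-range mapping of US pipelines; the planner's score t-bar is the
# mean compressed transmission over all scan-lines and depth samples.

#' Map Hounsfield units to the attenuation proxy
#'
#' `mu = max(1 + HU/1000, epsilon)` elementwise: water (0 HU) maps to 1, air
#' is floored at `epsilon` (making tissue/air interfaces near-total
#' reflectors), and only ratios of `mu` enter the transmission model.
#'
#' @param volume a [CtVolume-class]
#' @param epsilon positive floor (default 1e-3)
#' @return an [AttenuationField-class]
#' @examples
#' f <- huToMu(ctVolume(array(0, c(4, 4, 4))))
#' range(attenuation(f))
#' @export
huToMu <- function(volume, epsilon = 1e-3) {
    if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon <= 0)
        stop("epsilon must be a positive scalar")
    mu <- pmax(1 + volume@values / 1000, epsilon)
    new("AttenuationField", mu = mu, epsilon = epsilon,
        spacing = volume@spacing, origin = volume@origin,
        axes = volume@axes)
}

#' Acoustic transmission through a single interface
#'
#' `1 - ((z2 - z1)/(z2 + z1))^2` for impedance(-proxy) values z1, z2;
#' symmetric, 1 for matched media. Vectorised.
#'
#' @param z1,z2 positive impedance proxies
#' @return transmission coefficient(s) in \[0, 1\]
#' @examples
#' interfaceTransmission(1.48, 7.8)  # soft tissue / bone, ~0.536
#' @export
interfaceTransmission <- function(z1, z2) {
    if (any(z1 <= 0) || any(z2 <= 0))
        stop("impedance values must be positive")
    1 - ((z2 - z1) / (z2 + z1))^2
}

#' Log-compress a transmission value
#'
#' `log(1 + nu t)/log(1 + nu)`: monotone increasing, fixing 0 -> 0 and
#' 1 -> 1 for any nu > 0.
#'
#' @param t transmission value(s) in \[0, 1\]
#' @param nu positive compression factor (default 0.5)
#' @return compressed value(s) in \[0, 1\]
#' @examples
#' logCompress(0.5)  # ~0.5503
#' @export
logCompress <- function(t, nu = 0.5) {
    if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
    if (length(nu) != 1 || nu <= 0) stop("nu must be a positive scalar")
    log1p(nu * t) / log1p(nu)
}

# default ray-march step: half the minimum voxel spacing
defaultRayStep <- function(field) min(field@spacing) / 2

#' Cumulative log-compressed transmission along one ray
#'
#' Samples the attenuation proxy at depths `k * step` from the origin
#' (nearest voxel; outside the grid is air, i.e. the epsilon floor) and
#' returns the log-compressed cumulative transmission at every depth sample.
#' The profile starts at 1 and is non-increasing.
#'
#' @param field an [AttenuationField-class]
#' @param origin ray origin (world mm)
#' @param direction unit direction
#' @param depth maximum depth (mm)
#' @param step sample step (mm); default half the minimum voxel spacing
#' @param nu log-compression factor
#' @return numeric vector of compressed transmission values, one per depth
#'   sample, with the depths as the `depths` attribute
#' @export
rayTransmission <- function(field, origin, direction, depth,
                            step = NULL, nu = 0.5) {
    if (is.null(step)) step <- defaultRayStep(field)
    stopifnot(step > 0, abs(vecNorm(direction) - 1) < 1e-6)
    depths <- seq(0, by = step, length.out = floor(depth / step + 1e-9) + 1)
    pts <- matrix(origin, length(depths), 3, byrow = TRUE) +
        outer(depths, as.numeric(direction))
    mu <- sampleVolume(field, pts, outside = field@epsilon, mode = 0L)
    that <- compressCumulative(matrix(mu, ncol = 1), nu)[, 1]
    attr(that, "depths") <- depths
    that
}

# Cumulative compressed transmission for columns of mu samples
# (rows = depth samples, columns = rays).
compressCumulative <- function(muMat, nu) {
    if (nrow(muMat) == 1) {
        acc <- matrix(0, 1, ncol(muMat))
    } else {
        dmu <- diff(muMat)
        r2 <- (dmu / (muMat[-nrow(muMat), , drop = FALSE] +
                          muMat[-1, , drop = FALSE]))^2
        r2cum <- apply(r2, 2, cumsum)
        if (!is.matrix(r2cum)) r2cum <- matrix(r2cum, ncol = ncol(muMat))
        acc <- rbind(0, r2cum)
    }
    logCompress(exp(-acc), nu)
}

#' Mean transmission of a probe pose
#'
#' Evaluates the cumulative compressed transmission along every scan-line of
#' the fan at the pose and averages it over all scan-lines and depth samples
#' (the discrete form of the per-pose quality score t-bar).
#'
#' @param field an [AttenuationField-class]
#' @param geometry a [ProbeGeometry-class]
#' @param pose a [ProbePose-class]
#' @param step sample step (mm); default half the minimum voxel spacing
#' @param nu log-compression factor
#' @return a [TransmissionResult-class]
#' @examples
#' f <- huToMu(ctVolume(array(0, c(16, 16, 16)), spacing = c(4, 4, 4)))
#' pose <- poseFrom(c(32, 32, 0), c(32, 32, 60))
#' tbar(meanTransmission(f, probeGeometry(depth = 50), pose))
#' @export
meanTransmission <- function(field, geometry, pose, step = NULL, nu = 0.5) {
    if (is.null(step)) step <- defaultRayStep(field)
    nSamp <- floor(geometry@depth / step + 1e-9) + 1
    depths <- (seq_len(nSamp) - 1) * step
    sl <- scanlines(geometry)
    n <- geometry@nElements
    idx <- rep(seq_len(n), each = nSamp)
    l <- rep(depths, times = n)
    probePts <- sl$origins[idx, , drop = FALSE] +
        l * sl$directions[idx, , drop = FALSE]
    world <- sweep(probePts %*% t(pose@rotation), 2, pose@basePoint, "+")
    mu <- sampleVolume(field, world, outside = field@epsilon, mode = 0L)
    that <- compressCumulative(matrix(mu, nrow = nSamp), nu)
    new("TransmissionResult", perScanline = that, depths = depths,
        mean = mean(that), pose = pose)
}

# Batched t-bar over many poses through the compiled kernel; rotations and
# bases as matrices (row-major 9 values per pose / 3 values per pose).
tbarBatch <- function(field, geometry, rotations, bases, step, nu) {
    sl <- scanlines(geometry)
    tbarPosesCpp(as.numeric(field@mu), dim(field@mu), field@spacing,
                 field@origin, field@axes, sl$origins, sl$directions,
                 geometry@depth, step, nu, rotations, bases,
                 field@epsilon)
}

#' Best mean transmission per candidate surface point
#'
#' For every candidate surface point, evaluates t-bar on the roll-angle grid
#' and keeps the per-point maximum and its roll angle: the surface
#' transmission map highlighting the acoustic windows for a target.
#'
#' @param field an [AttenuationField-class]
#' @param geometry a [ProbeGeometry-class]
#' @param candidates a [CandidateSet-class] for the target
#' @param surface the [SurfacePointCloud-class] the candidates index into
#' @param config a [PlannerConfig-class] (roll grid, ray step, nu)
#' @return data.frame with columns `index`, `x`, `y`, `z`, `t_bar_best`,
#'   `phi_best_deg`
#' @seealso [writeSurfaceMapCsv()], [writeSurfacePly()]
#' @export
surfaceTransmissionMap <- function(field, geometry, candidates, surface,
                                   config = plannerConfig()) {
    tb <- candidateTbarMatrix(field, geometry, candidates, surface, config)
    bestIdx <- apply(tb, 1, which.max)
    phis <- angleGrid(config)
    data.frame(index = candidates@indices,
               x = surface@points[candidates@indices, 1],
               y = surface@points[candidates@indices, 2],
               z = surface@points[candidates@indices, 3],
               t_bar_best = tb[cbind(seq_len(nrow(tb)), bestIdx)],
               phi_best_deg = phis[bestIdx] * 180 / pi)
}

#' Write a surface transmission map as CSV
#'
#' @param map data.frame from [surfaceTransmissionMap()]
#' @param path output path
#' @return the path, invisibly
#' @export
writeSurfaceMapCsv <- function(map, path) {
    write.csv(map, path, row.names = FALSE)
    invisible(path)
}
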