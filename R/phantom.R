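# Synthetic torso phantom: an elliptic soft-tissue body cylinder in air,
# bone-density rib arcs in axial planes with intercostal gaps, and a
# labelled soft-tissue organ ellipsoid beneath the ribs. The intercostal
# gaps are the acoustic windows the planner must discover; rib planes are
# placed symmetrically about the organ centre so that one gap is centred on
# it.

#' Generate a synthetic torso phantom
#'
#' Builds a CT volume (HU), a co-registered organ label volume (label 1) and
#' a set of target points drawn uniformly from organ voxels eroded by two
#' voxels (avoiding boundary targets with ambiguous coverage). Fully
#' deterministic given `config@seed`.
#'
#' @param config a [PhantomConfig-class]
#' @return a list with elements `ct` ([CtVolume-class]), `labels`
#'   ([LabelVolume-class]) and `targets` (n x 3 matrix of world mm)
#' @examples
#' ph <- generatePhantom(phantomConfig(volumeShape = c(32, 32, 24),
#'                                     spacingMm = c(3, 3, 3),
#'                                     ribCount = 0L, noiseSigma = 0))
#' gridDim(ph$ct)
#' @export
generatePhantom <- function(config) {
    stopifnot(is(config, "PhantomConfig"))
    validObject(config)
    d <- config@volumeShape
    sp <- config@spacingMm
    origin <- sp / 2
    # world coordinates of voxel centres, one vector per axis
    xs <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
    ys <- origin[2] + (seq_len(d[2]) - 1) * sp[2]
    zs <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
    centre <- bodyCentre(config)
    relX2 <- ((xs - centre[1]) / config@bodyHalfAxes[1])^2
    relY2 <- ((ys - centre[2]) / config@bodyHalfAxes[2])^2
    bodyXY <- outer(relX2, relY2, "+") <= 1
    hu <- array(config@backgroundHu, d)
    hu[rep(bodyXY, times = d[3])] <- config@bodyHu

    ox2 <- ((xs - config@organCentre[1]) / config@organHalfAxes[1])^2
    oy2 <- ((ys - config@organCentre[2]) / config@organHalfAxes[2])^2
    oz2 <- ((zs - config@organCentre[3]) / config@organHalfAxes[3])^2
    organ <- outer(outer(ox2, oy2, "+"), oz2, "+") <= 1
    hu[organ] <- config@organHu

    if (config@ribCount > 0)
        hu <- stampRibs(hu, config, xs, ys, zs, centre, bodyXY)

    if (config@noiseSigma > 0) {
        noise <- withLocalSeed(config@seed,
                               rnorm(prod(d), sd = config@noiseSigma))
        hu <- hu + array(noise, d)
    }

    ct <- ctVolume(hu, spacing = sp, origin = origin)
    labels <- labelVolume(array(as.integer(organ), d), spacing = sp,
                          origin = origin, labelMap = c("1" = "organ"))
    targets <- sampleOrganTargets(organ, config, sp, origin)
    list(ct = ct, labels = labels, targets = targets)
}

# Rib arcs: partial elliptical tori in axial planes. Each rib centreline is
# the body ellipse scaled by ribScale, restricted to +/- ribArcDeg/2 around
# the anterior (+y) direction; the tube is stamped as a union of spheres at
# ~1 mm centreline pitch. Rib planes are symmetric about the organ centre z
# with pitch gap + 2 * radius, so an intercostal gap is centred on it.
stampRibs <- function(hu, config, xs, ys, zs, centre, bodyXY) {
    d <- dim(hu)
    sp <- config@spacingMm
    pitch <- config@ribGap + 2 * config@ribRadius
    k <- seq_len(config@ribCount) - (config@ribCount + 1) / 2
    ribZ <- config@organCentre[3] + k * pitch
    psi <- seq(-config@ribArcDeg / 2, config@ribArcDeg / 2,
               by = 1) * pi / 180
    cx <- centre[1] + config@ribScale * config@bodyHalfAxes[1] * sin(psi)
    cy <- centre[2] + config@ribScale * config@bodyHalfAxes[2] * cos(psi)
    rad <- config@ribRadius
    nbr <- ceiling(rad / sp)
    for (z0 in ribZ) {
        for (j in seq_along(psi)) {
            # voxel index window around the centreline point
            ix <- which(abs(xs - cx[j]) <= rad + sp[1])
            iy <- which(abs(ys - cy[j]) <= rad + sp[2])
            iz <- which(abs(zs - z0) <= rad + sp[3])
            if (!length(ix) || !length(iy) || !length(iz)) next
            dx2 <- (xs[ix] - cx[j])^2
            dy2 <- (ys[iy] - cy[j])^2
            dz2 <- (zs[iz] - z0)^2
            inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad^2
            blk <- hu[ix, iy, iz, drop = FALSE]
            bodyBlk <- array(bodyXY[ix, iy], dim(inside))
            blk[inside & bodyBlk] <- config@ribHu
            hu[ix, iy, iz] <- blk
        }
    }
    hu
}

sampleOrganTargets <- function(organ, config, sp, origin) {
    core <- binaryErode6(binaryErode6(organ))
    idx <- which(core)
    if (!length(idx))
        stop("organ too small to erode for target sampling")
    n <- min(config@nTargets, length(idx))
    pick <- withLocalSeed(config@seed + 1L,
                          sample(length(idx), n, replace = FALSE))
    sel <- idx[sort(pick)]
    d <- dim(organ)
    i0 <- cbind((sel - 1) %% d[1],
                ((sel - 1) %/% d[1]) %% d[2],
                (sel - 1) %/% (d[1] * d[2]))
    voxelToWorld(i0, sp, origin, diag(3))
}

#' Generate a two-layer slab volume
#'
#' An axis-aligned volume, constant within each of two layers stacked along
#' the third axis, with the interface at a given depth; layer membership is
#' decided by voxel-centre depth. Useful for checking the single-interface
#' closed form of the transmission model.
#'
#' @param huValues numeric(2): HU of the first (shallow) and second layer
#' @param interfaceDepth depth of the interface along the third axis (mm)
#' @param shape integer(3) voxels per axis
#' @param spacing numeric(3) voxel size (mm)
#' @return a [CtVolume-class] spanning world z in \[0, shape3 * spacing3\]
#' @examples
#' slab <- generateTwoLayerSlab(c(0, 1000), 30)
#' @export
generateTwoLayerSlab <- function(huValues, interfaceDepth,
                                 shape = c(24L, 24L, 60L),
                                 spacing = c(1, 1, 1)) {
    stopifnot(length(huValues) == 2)
    if (interfaceDepth <= 0 || interfaceDepth >= shape[3] * spacing[3])
        stop("interface depth must lie inside the volume")
    origin <- spacing / 2
    zc <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
    hu <- array(rep(ifelse(zc < interfaceDepth, huValues[1], huValues[2]),
                    each = shape[1] * shape[2]), shape)
    ctVolume(hu, spacing = spacing, origin = origin)
}
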