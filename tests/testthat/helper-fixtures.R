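# Shared fixtures (built in code, memoised per test run) and independent
# oracles used to cross-check the planner and transmission paths.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
    if (!exists(name, envir = .fixtures))
        assign(name, expr, envir = .fixtures)
    get(name, envir = .fixtures)
}

# Small rib phantom for unit tests: same structure as the default, coarser
# grid so everything stays fast.
smallRibConfig <- function(...) {
    phantomConfig(volumeShape = c(64L, 64L, 48L), spacingMm = c(2, 2, 2),
                  bodyHalfAxes = c(55, 42), organHalfAxes = c(26, 14, 20),
                  ribCount = 4L, ribGap = 8, noiseSigma = 10, seed = 7L,
                  ...)
}

smallRibPhantom <- function() {
    memoFixture("smallRibPhantom",
                suppressMessages(generatePhantom(smallRibConfig())))
}

smallRibSurface <- function() {
    memoFixture("smallRibSurface",
                extractSurface(smallRibPhantom()$ct, density = 0.012))
}

smallRibField <- function() {
    memoFixture("smallRibField", huToMu(smallRibPhantom()$ct))
}

defaultRibPhantom <- function() {
    memoFixture("defaultRibPhantom",
                suppressMessages(generatePhantom(phantomConfig())))
}

# Sphere phantom: soft-tissue ball in air.
spherePhantom <- function(radius = 40) {
    memoFixture("spherePhantom", {
        d <- c(56L, 56L, 56L)
        sp <- c(2, 2, 2)
        origin <- sp / 2
        ax <- origin[1] + (seq_len(d[1]) - 1) * sp[1]
        centre <- d * sp / 2
        dist2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, "+"),
                       (ax - centre[3])^2, "+")
        hu <- array(-1000, d)
        hu[dist2 <= radius^2] <- 40
        list(ct = ctVolume(hu, spacing = sp, origin = origin),
             centre = centre, radius = radius)
    })
}

# Independent voxel ray-march: does any sample along the ray (within the
# body of the volume) exceed huMin? Uses plain R index arithmetic.
rayHitsHu <- function(ct, origin, direction, maxDepth, huMin = 300,
                      step = 0.5) {
    depths <- seq(0, maxDepth, by = step)
    pts <- matrix(origin, length(depths), 3, byrow = TRUE) +
        outer(depths, as.numeric(direction))
    idx <- sweep(pts, 2, worldOrigin(ct), "-") %*%
        diag(1 / voxelSpacing(ct))
    idx <- floor(idx + 0.5) + 1
    d <- gridDim(ct)
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
        idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
    if (!any(ok)) return(FALSE)
    hu <- hounsfield(ct)[idx[ok, , drop = FALSE]]
    any(hu > huMin)
}

# Brute-force candidate enumeration applying the two hard-constraint
# predicates point by point.
bfCandidates <- function(surface, target, geometry, config) {
    pts <- surfacePoints(surface)
    nrm <- surfaceNormals(surface)
    keep <- logical(nrow(pts))
    for (i in seq_len(nrow(pts))) {
        d <- target - pts[i, ]
        dist <- sqrt(sum(d^2))
        if (dist >= slot(geometry, "depth")) next
        da <- d / dist
        cosA <- sum(da * (-nrm[i, ]))
        keep[i] <- acos(min(1, max(-1, cosA))) * 180 / pi <=
            slot(config, "alphaDeg")
    }
    which(keep)
}

# t-bar via the R evaluation path (meanTransmission) -- an independent
# summation route from the planner's compiled batch kernel.
bfTbar <- function(field, geometry, base, target, phi, config) {
    pose <- poseFrom(base, target, roll = phi,
                     referenceUp = slot(config, "referenceUp"))
    step <- slot(config, "rayStepMm")
    if (is.na(step)) step <- min(voxelSpacing(field)) / 2
    tbar(meanTransmission(field, geometry, pose, step = step,
                          nu = slot(config, "nu")))
}

# Exhaustive joint argmax over candidates x roll grid with the planner's
# tie-break (strict improvement; candidates in index order, angles
# ascending).
bfSingleView <- function(field, surface, target, geometry, config) {
    cand <- bfCandidates(surface, target, geometry, config)
    phis <- seq(0, pi - 1e-12,
                by = slot(config, "angleGridStepDeg") * pi / 180)
    best <- list(score = -Inf)
    for (ci in cand) for (phi in phis) {
        tb <- bfTbar(field, geometry, surfacePoints(surface)[ci, ], target,
                     phi, config)
        if (tb > best$score)
            best <- list(score = tb, index = ci, phi = phi)
    }
    best
}

# Exhaustive joint argmax over the shared base point and the full roll-grid
# product set (enumerated via the per-target score tables; the product over
# targets factorises, and enumerating the product set explicitly confirms
# it).
bfMultiView <- function(field, surface, targets, geometry, config) {
    sets <- lapply(seq_len(nrow(targets)), function(i)
        bfCandidates(surface, targets[i, ], geometry, config))
    common <- sort(Reduce(intersect, sets))
    phis <- seq(0, pi - 1e-12,
                by = slot(config, "angleGridStepDeg") * pi / 180)
    nT <- nrow(targets)
    best <- list(score = -Inf)
    for (ci in common) {
        tabs <- lapply(seq_len(nT), function(i)
            vapply(phis, function(phi)
                bfTbar(field, geometry, surfacePoints(surface)[ci, ],
                       targets[i, ], phi, config), numeric(1)))
        combos <- expand.grid(rep(list(seq_along(phis)), nT))
        prods <- rep(1, nrow(combos))
        for (i in seq_len(nT)) prods <- prods * tabs[[i]][combos[, i]]
        w <- which.max(prods)
        if (prods[w] > best$score)
            best <- list(score = prods[w], index = ci,
                         phi = phis[unlist(combos[w, ])])
    }
    best
}

expect_unit_vector <- function(v, tol = 1e-9) {
    expect_lt(abs(sqrt(sum(v^2)) - 1), tol)
}
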