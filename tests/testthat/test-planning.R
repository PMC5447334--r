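test_that("candidate enumeration equals the brute-force predicates", {
    sph <- spherePhantom()
    surf <- extractSurface(sph$ct, density = 0.05)
    geom <- probeGeometry()
    cfg <- plannerConfig()
    target <- sph$centre + c(10, -8, 5)
    cand <- candidateSurfacePoints(surf, target, geom, cfg)
    expect_identical(candidateIndices(cand),
                     as.integer(bfCandidates(surf, target, geom, cfg)))
    # depth constraint: every surface point too far -> diagnostic error
    far <- sph$centre + c(0, 0, 500)
    err <- tryCatch(candidateSurfacePoints(surf, far, geom, cfg),
                    awNoWindowError = function(e) e)
    expect_s3_class(err, "awNoWindowError")
    expect_gt(err$minDistance, slot(geom, "depth"))
})

test_that("the coupling-angle constraint follows flat-surface geometry", {
    # flat surface at z = 0, outward normals +z, target 50 mm below origin
    xs <- seq(-80, 80, by = 10)
    grid <- as.matrix(expand.grid(x = xs, y = xs))
    pts <- cbind(grid, 0)
    nrm <- matrix(rep(c(0, 0, 1), nrow(pts)), ncol = 3, byrow = TRUE)
    surf <- methods::new("SurfacePointCloud", points = pts, normals = nrm,
                         sourceSpacing = c(1, 1, 1))
    cand <- candidateSurfacePoints(surf, c(0, 0, -50), probeGeometry(),
                                   plannerConfig())
    r <- sqrt(rowSums(pts[candidateIndices(cand), 1:2, drop = FALSE]^2))
    expect_true(all(r < 50 * tan(30 * pi / 180) + 1e-9))
    p0 <- which(pts[, 1] == 0 & pts[, 2] == 0)
    expect_true(p0 %in% candidateIndices(cand))       # angle 0
    p60 <- which(pts[, 1] == 60 & pts[, 2] == 0)      # atan(60/50) ~ 50 deg
    expect_false(p60 %in% candidateIndices(cand))
})

test_that("single-view planning equals the exhaustive joint argmax", {
    surf <- smallRibSurface()
    expect_lte(nrow(surfacePoints(surf)), 500)
    f <- smallRibField()
    geom <- probeGeometry()
    cfg <- plannerConfig(angleGridStepDeg = 15)
    target <- smallRibPhantom()$targets[1, ]
    plan <- planSingleView(f, surf, target, geom, cfg)
    oracle <- bfSingleView(f, surf, target, geom, cfg)
    winner <- plan@candidates[which.max(plan@candidates$t_bar), ]
    expect_equal(basePoint(poses(plan)[[1]]),
                 unname(surfacePoints(surf)[oracle$index, ]))
    expect_equal(plan@phiDeg, oracle$phi * 180 / pi)
    expect_equal(planScores(plan), oracle$score, tolerance = 1e-9)
})

test_that("multi-view planning matches the joint product argmax", {
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    cfg <- plannerConfig(angleGridStepDeg = 15)
    targets <- smallRibPhantom()$targets[1:3, ]
    plan <- planMultiView(f, surf, targets, geom, cfg)
    oracle <- bfMultiView(f, surf, targets, geom, cfg)
    expect_equal(basePoint(poses(plan)[[1]]),
                 unname(surfacePoints(surf)[oracle$index, ]))
    expect_equal(plan@phiDeg, oracle$phi * 180 / pi, tolerance = 1e-9)
    expect_equal(exp(plan@objective), oracle$score, tolerance = 1e-9)
    # all poses share the base point
    bp <- vapply(poses(plan), basePoint, numeric(3))
    expect_equal(max(abs(bp - bp[, 1])), 0)
    # admissibility re-check on the returned pose
    cand <- candidateSurfacePoints(surf, targets[1, ], geom, cfg)
    d <- sqrt(sum((targets[1, ] - basePoint(poses(plan)[[1]]))^2))
    expect_lt(d, slot(geom, "depth"))
})

test_that("multi-view with one target reduces to single-view planning", {
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    cfg <- plannerConfig(angleGridStepDeg = 15)
    target <- smallRibPhantom()$targets[2, ]
    single <- planSingleView(f, surf, target, geom, cfg)
    multi <- planMultiView(f, surf, matrix(target, 1, 3), geom, cfg)
    expect_identical(basePoint(poses(single)[[1]]),
                     basePoint(poses(multi)[[1]]))
    expect_identical(poseRotation(poses(single)[[1]]),
                     poseRotation(poses(multi)[[1]]))
    expect_identical(planScores(single), planScores(multi))
    expect_identical(single@phiDeg, multi@phiDeg)
})

test_that("homogeneous media tie-break to the lowest index and zero roll", {
    sph <- spherePhantom()
    homo <- huToMu(ctVolume(array(40, c(70, 70, 70)), spacing = c(8, 8, 8),
                            origin = c(-200, -200, -200)))
    surf <- extractSurface(sph$ct, density = 0.01)
    geom <- probeGeometry()
    cfg <- plannerConfig(angleGridStepDeg = 45)
    plan <- planSingleView(homo, surf, sph$centre, geom, cfg)
    cand <- candidateSurfacePoints(surf, sph$centre, geom, cfg)
    expect_equal(planScores(plan), 1)
    expect_equal(plan@phiDeg, 0)
    expect_equal(basePoint(poses(plan)[[1]]),
                 unname(surfacePoints(surf)[candidateIndices(cand)[1], ]))
})

test_that("planning is deterministic across repeated runs", {
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    cfg <- plannerConfig(angleGridStepDeg = 30)
    target <- smallRibPhantom()$targets[1, ]
    a <- planSingleView(f, surf, target, geom, cfg)
    b <- planSingleView(f, surf, target, geom, cfg)
    expect_identical(basePoint(poses(a)[[1]]), basePoint(poses(b)[[1]]))
    expect_identical(planScores(a), planScores(b))
    expect_identical(a@candidates, b@candidates)
})

test_that("naive planning picks the nearest point with a surface-keyed frame", {
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    target <- smallRibPhantom()$targets[1, ]
    plan <- planNaiveSingle(surf, target, geom, f)
    pts <- surfacePoints(surf)
    dists <- sqrt(rowSums(sweep(pts, 2, target)^2))
    expect_equal(basePoint(poses(plan)[[1]]),
                 unname(pts[which.min(dists), ]))
    pose <- poses(plan)[[1]]
    n <- surfaceNormals(surf)[which.min(dists), ]
    expect_lt(abs(sum(lateralDir(pose) * axialDir(pose))), 1e-9)
    expect_lt(abs(sum(lateralDir(pose) * n)), 1e-9)
    expect_unit_vector(lateralDir(pose))
    expect_true(is.na(plan@phiDeg))
})

test_that("ours dominates naive on a target hidden beneath a rib", {
    ph <- smallRibPhantom()
    cfg <- smallRibConfig()
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    pcfg <- plannerConfig(angleGridStepDeg = 15)
    # target directly under the first rib plane above the organ centre
    pitch <- 2 * slot(cfg, "ribRadius") + slot(cfg, "ribGap")
    target <- slot(cfg, "organCentre") + c(0, 0, pitch / 2)
    ours <- planSingleView(f, surf, target, geom, pcfg)
    naive <- planNaiveSingle(surf, target, geom, f, pcfg)
    npose <- poses(naive)[[1]]
    expect_true(rayHitsHu(ph$ct, basePoint(npose), axialDir(npose), 60))
    expect_gt(planScores(ours), planScores(naive))
})

test_that("naive multi-view frames follow the trajectory rejection", {
    surf <- smallRibSurface()
    geom <- probeGeometry()
    targets <- smallRibPhantom()$targets[1:3, ]
    plan <- planNaiveMulti(surf, targets, geom)
    dT <- (targets[3, ] - targets[1, ])
    dT <- dT / sqrt(sum(dT^2))
    for (pose in poses(plan)) {
        de <- elevationalDir(pose)
        da <- axialDir(pose)
        expect_lt(abs(sum(de * da)), 1e-9)
        expect_unit_vector(de)
        rej <- dT - da * sum(da * dT)
        expect_equal(de, rej / sqrt(sum(rej^2)), tolerance = 1e-9)
    }
    # trajectory parallel to an axial axis is rejected with the target index
    pts <- matrix(c(0, 0, 0), 1, 3)
    oneSurf <- methods::new("SurfacePointCloud", points = pts,
                            normals = matrix(c(0, 0, 1), 1, 3),
                            sourceSpacing = c(1, 1, 1))
    expect_error(planNaiveMulti(oneSurf, rbind(c(0, 0, -50), c(0, 0, -90)),
                                geom, trajectoryDir = c(0, 0, -1)),
                 "target 1")
})
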