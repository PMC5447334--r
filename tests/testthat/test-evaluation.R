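test_that("axis-aligned pose slices reproduce the voxel plane", {
    ph <- generatePhantom(phantomConfig(volumeShape = c(48, 48, 32),
                                        spacingMm = c(3, 3, 3),
                                        bodyHalfAxes = c(55, 45),
                                        organHalfAxes = c(25, 13, 18),
                                        ribCount = 0L, noiseSigma = 0))
    geom <- probeGeometry(depth = 60)
    # lateral = +x, axial = -y: slice lives in the axial z-plane of the base
    base <- c(72, 105, 48)
    da <- c(0, -1, 0); dl <- c(1, 0, 0)
    pose <- methods::new("ProbePose",
                         rotation = cbind(dl, AcousticWindow:::crossProduct(
                             da, dl), da, deparse.level = 0),
                         basePoint = base)
    slice <- extractPoseSlice(ph$ct, pose, geom, pixelSpacing = 3)
    grid <- expand.grid(u = slice@u, v = slice@v)
    ref <- sampleTrilinear(ph$ct, cbind(base[1] + grid$u,
                                        base[2] - grid$v, base[3]))
    expect_equal(as.numeric(slice@pixels), ref, tolerance = 1e-9)
})

test_that("the fan mask is the curvilinear sector, widening with depth", {
    geom <- probeGeometry(arrayRadius = 40, fovAngle = 70, depth = 100)
    pose <- poseFrom(c(0, 0, 0), c(0, 0, 100))
    slice <- extractPoseSlice(ctVolume(array(0, c(8, 8, 8))), pose, geom,
                              pixelSpacing = 2)
    # independent per-pixel sector predicate
    n <- 0L
    for (i in seq_along(slice@u)) for (j in seq_along(slice@v)) {
        u <- slice@u[i]; v <- slice@v[j]
        rad <- sqrt(u^2 + (v + 40)^2)
        ok <- rad >= 40 && rad <= 140 &&
            abs(atan2(u, v + 40)) <= 35 * pi / 180
        if (ok) n <- n + 1L
    }
    expect_identical(slice@nIn, n)
    # sector property: rows widen with depth through the fan body (the
    # width peaks where the bounding arc meets the aperture edge, at
    # v = (r + depth) cos(fov/2) - r, and the bottom row is the arc tip)
    rowWidth <- colSums(slice@fanMask)
    expect_gt(rowWidth[which(slice@v == 70)], rowWidth[which(slice@v == 10)])
    expect_gt(rowWidth[which(slice@v == 40)], rowWidth[which(slice@v == 10)])
})

test_that("tissue ratios count in-fan pixels exactly", {
    geom <- probeGeometry(depth = 80)
    pose <- poseFrom(c(0, 0, 0), c(0, 0, 80))
    water <- ctVolume(array(0, c(60, 60, 50)), spacing = c(3, 3, 3),
                      origin = c(-90, -90, -15))
    slice <- extractPoseSlice(water, pose, geom, pixelSpacing = 2)
    expect_equal(ratioNonSoftTissue(slice), 0)
    bone <- ctVolume(array(1000, c(60, 60, 50)), spacing = c(3, 3, 3),
                     origin = c(-90, -90, -15))
    sliceB <- extractPoseSlice(bone, pose, geom, pixelSpacing = 2)
    expect_equal(ratioNonSoftTissue(sliceB), 1)
    # constructed slice: exactly 40% of in-fan pixels at bone HU
    px <- slice@pixels
    px[] <- 40
    inFan <- which(slice@fanMask)
    k <- floor(0.4 * length(inFan))
    px[inFan[seq_len(k)]] <- 900
    built <- methods::new("PoseSlice", pixels = px,
                          fanMask = slice@fanMask, u = slice@u,
                          v = slice@v, pixelSpacing = 2, pose = pose,
                          nIn = slice@nIn)
    expect_equal(ratioNonSoftTissue(built), k / length(inFan))
    # partition: non-soft + soft = 1
    hu <- slice@pixels[slice@fanMask]
    soft <- mean(hu >= -100 & hu <= 150)
    expect_equal(ratioNonSoftTissue(slice) + soft, 1)
    expect_error(ratioNonSoftTissue(slice, beta1 = 150, beta2 = -100),
                 "beta1")
})

test_that("organ coverage follows the label content of the fan", {
    geom <- probeGeometry(depth = 60)
    pose <- poseFrom(c(0, 0, 0), c(0, 0, 60))
    sp <- c(2, 2, 2); org <- c(-60, -60, -10)
    inside <- labelVolume(array(1L, c(60, 60, 40)), spacing = sp,
                          origin = org)
    outside <- labelVolume(array(0L, c(60, 60, 40)), spacing = sp,
                           origin = org)
    ct <- ctVolume(array(0, c(60, 60, 40)), spacing = sp, origin = org)
    slice <- extractPoseSlice(ct, pose, geom, pixelSpacing = 1)
    expect_equal(ratioSegmentation(slice, inside), 1)
    expect_equal(ratioSegmentation(slice, outside), 0)
    expect_error(ratioSegmentation(slice, inside, organLabel = 9),
                 "label id")
    # half-plane label: expected fraction from the mask geometry itself
    half <- array(0L, c(60, 60, 40))
    half[, , ] <- 0L
    zc <- org[3] + (seq_len(40) - 0.5) * sp[3]
    half[, , zc > 30] <- 1L   # axial depth beyond 30 mm
    halfLab <- labelVolume(half, spacing = sp, origin = org)
    r <- ratioSegmentation(slice, halfLab)
    expected <- sum(slice@fanMask[, slice@v > 30]) / slice@nIn
    # nearest-neighbour label sampling can move the boundary by half a
    # label voxel (one pixel row) on top of the counting row itself
    rowFrac <- max(colSums(slice@fanMask)) / slice@nIn
    expect_lt(abs(r - expected), 2.5 * rowFrac + 1e-9)
})

test_that("rigidly translating volume and pose leaves ratios unchanged", {
    ph <- smallRibPhantom()
    geom <- probeGeometry()
    pose <- poseFrom(c(64, 99, 48), c(64, 60, 48), roll = 0.7)
    shift <- c(13, -7, 4)
    movedCt <- ctVolume(hounsfield(ph$ct), spacing = voxelSpacing(ph$ct),
                        origin = worldOrigin(ph$ct) + shift)
    movedLab <- labelVolume(labelArray(ph$labels),
                            spacing = voxelSpacing(ph$labels),
                            origin = worldOrigin(ph$labels) + shift)
    movedPose <- methods::new("ProbePose", rotation = poseRotation(pose),
                              basePoint = basePoint(pose) + shift)
    s1 <- extractPoseSlice(ph$ct, pose, geom)
    s2 <- extractPoseSlice(movedCt, movedPose, geom)
    expect_lt(abs(ratioNonSoftTissue(s1) - ratioNonSoftTissue(s2)), 1e-3)
    expect_lt(abs(ratioSegmentation(s1, ph$labels) -
                      ratioSegmentation(s2, movedLab)), 1e-3)
})

test_that("plan comparison aggregates per method with zero SD singletons", {
    ph <- smallRibPhantom()
    surf <- smallRibSurface()
    f <- smallRibField()
    geom <- probeGeometry()
    target <- ph$targets[1, ]
    naive <- planNaiveSingle(surf, target, geom, f)
    rep1 <- comparePlans(ph$ct, ph$labels, list(naive), geom)
    expect_equal(nrow(reportTable(rep1)), 1)
    agg <- reportAggregates(rep1)
    expect_equal(agg$r_ct_sd, 0)
    expect_equal(agg$r_ct_mean, reportTable(rep1)$r_ct)
    # duplicated pose: same mean, SD still 0
    rep2 <- comparePlans(ph$ct, ph$labels, list(naive, naive), geom)
    agg2 <- reportAggregates(rep2)
    expect_equal(agg2$r_ct_mean, agg$r_ct_mean)
    expect_equal(agg2$r_ct_sd, 0)
    expect_true(all(reportTable(rep2)$r_ct >= 0 &
                        reportTable(rep2)$r_ct <= 1))
})
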