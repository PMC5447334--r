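test_that("body mask is the largest component above threshold, closed", {
    ph <- generatePhantom(phantomConfig(volumeShape = c(48, 48, 32),
                                        spacingMm = c(3, 3, 3),
                                        bodyHalfAxes = c(55, 45),
                                        organHalfAxes = c(25, 13, 18),
                                        ribCount = 0L, noiseSigma = 0))
    mask <- extractBodyMask(ph$ct, thresholdHu = -300)
    expect_identical(mask, hounsfield(ph$ct) > -300)  # convex body: closing
    expect_error(extractBodyMask(ctVolume(array(-1000, c(8, 8, 8)))),
                 "no body found")
    # two disjoint blobs: only the larger survives
    hu <- array(-1000, c(20, 20, 8))
    hu[3:10, 3:10, 3:6] <- 40
    hu[14:16, 14:16, 3:4] <- 40
    m2 <- extractBodyMask(ctVolume(hu, spacing = c(2, 2, 2)))
    expect_true(all(!m2[14:16, 14:16, ]))
    expect_true(any(m2[3:10, 3:10, ]))
})

test_that("flat slab yields near-axis normals and density-matched counts", {
    hu <- array(-1000, c(50, 50, 30))
    hu[6:45, 6:45, 5:15] <- 40  # 40x40 mm top face at 1 mm spacing
    v <- ctVolume(hu, spacing = c(1, 1, 1))
    surf <- extractSurface(v, density = 0.25)
    pts <- surfacePoints(surf)
    nrm <- surfaceNormals(surf)
    top <- pts[, 3] > 14 & pts[, 1] > 10 & pts[, 1] < 41 &
        pts[, 2] > 10 & pts[, 2] < 41
    expect_gt(sum(top), 50)
    ang <- acos(pmin(1, nrm[top, 3])) * 180 / pi
    expect_lt(max(ang), 5)
    # top-face point count ~ area x density (interior 30x30 window)
    inner <- top & pts[, 1] > 10.5 & pts[, 1] < 40.5 &
        pts[, 2] > 10.5 & pts[, 2] < 40.5
    expected <- 30 * 30 * 0.25
    expect_gt(sum(inner), expected * 0.8)
    expect_lt(sum(inner), expected * 1.2)
})

test_that("sphere surface points sit one voxel diagonal from the radius", {
    sph <- spherePhantom()
    surf <- extractSurface(sph$ct, density = 0.1)
    dists <- sqrt(rowSums(sweep(surfacePoints(surf), 2, sph$centre)^2))
    diagLen <- sqrt(sum(voxelSpacing(sph$ct)^2))
    expect_lt(max(abs(dists - sph$radius)), diagLen)
})

test_that("normals point outward: a 1 mm step along them leaves the mask", {
    ph <- smallRibPhantom()
    surf <- extractSurface(ph$ct, density = 0.05)
    mask <- extractBodyMask(ph$ct)
    mv <- AcousticWindow:::sampleVolume(
        ctVolume(mask * 1 * 1000, spacing = voxelSpacing(ph$ct),
                 origin = worldOrigin(ph$ct)),
        surfacePoints(surf) + surfaceNormals(surf), outside = 0, mode = 0L)
    expect_gte(mean(mv < 500), 0.99)
    nn <- sqrt(rowSums(surfaceNormals(surf)^2))
    expect_lt(max(abs(nn - 1)), 1e-6)
})

test_that("translating the volume translates the cloud exactly", {
    ph <- smallRibPhantom()
    shift <- c(11.5, -3.25, 7)
    moved <- ctVolume(hounsfield(ph$ct), spacing = voxelSpacing(ph$ct),
                      origin = worldOrigin(ph$ct) + shift)
    a <- extractSurface(ph$ct, density = 0.02)
    b <- extractSurface(moved, density = 0.02)
    expect_equal(surfacePoints(b),
                 sweep(surfacePoints(a), 2, shift, "+"), tolerance = 1e-9)
    expect_equal(surfaceNormals(b), surfaceNormals(a), tolerance = 1e-9)
})

test_that("degenerate masks are rejected", {
    m <- array(FALSE, c(8, 8, 8))
    m[4, 4, 4] <- TRUE
    expect_error(extractSurfacePoints(m, ctVolume(array(0, c(8, 8, 8)))),
                 "degenerate")
})

test_that("PLY export writes a readable header and one row per point", {
    surf <- smallRibSurface()
    path <- tempfile(fileext = ".ply")
    writeSurfacePly(surf, path, scalar = rep(0.5, nrow(surfacePoints(surf))))
    lines <- readLines(path)
    expect_identical(lines[1], "ply")
    expect_identical(lines[3],
                     paste("element vertex", nrow(surfacePoints(surf))))
    expect_length(lines, 11 + nrow(surfacePoints(surf)))
})
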