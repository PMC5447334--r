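# Probe geometry and pose algebra. Probe frame convention: +z axial (into
# tissue), +x lateral, +y elevational. Scan-lines live in the axial-lateral
# plane (2D image model); 3D trajectories are sequences of such planes.

#' Scan-line origins and directions in the probe frame
#'
#' Element angles are uniformly spaced over \[-fov/2, +fov/2\]; elements sit
#' on the curved array (radius of curvature `arrayRadius`) with the central
#' element at the probe-frame origin, and each scan-line points radially
#' outward at its element angle. All coordinates have zero elevational (y)
#' component.
#'
#' @param geometry a [ProbeGeometry-class]
#' @return list with `origins` and `directions`, each nElements x 3
#' @examples
#' sl <- scanlines(probeGeometry(nElements = 5L))
#' sl$directions[3, ]  # central line along +z
#' @export
scanlines <- function(geometry) {
    stopifnot(is(geometry, "ProbeGeometry"))
    half <- geometry@fovAngle / 2 * pi / 180
    theta <- seq(-half, half, length.out = geometry@nElements)
    r <- geometry@arrayRadius
    list(origins = cbind(r * sin(theta), 0, r * (cos(theta) - 1)),
         directions = cbind(sin(theta), 0, cos(theta)))
}

#' Construct a probe pose from base point, target and roll angle
#'
#' The axial axis points from the base surface point to the target,
#' `d_a = (target - base)/|target - base|`. At roll zero the lateral axis is
#' the normalised rejection of the reference up vector from `d_a`; a general
#' roll applies the rotation about `d_a` by `roll` radians to that frame.
#' Because the image plane is invariant under an in-plane flip, roll is
#' pi-periodic and planners search \[0, pi).
#'
#' @param base surface point s (world mm)
#' @param target target point (world mm)
#' @param roll roll angle about the axial axis, radians
#' @param referenceUp world unit vector keying roll zero; if parallel to the
#'   axial axis, the next global axis is used (deterministically, with a
#'   message)
#' @return a [ProbePose-class]
#' @examples
#' p <- poseFrom(c(0, 0, 0), c(0, 0, 100), roll = 0)
#' axialDir(p)
#' @export
poseFrom <- function(base, target, roll = 0, referenceUp = c(0, 0, 1)) {
    base <- as.numeric(base)
    target <- as.numeric(target)
    if (vecNorm(target - base) < 1e-9)
        stop("degenerate pose: target coincides with the base point")
    da <- unitVector(target - base)
    up <- as.numeric(referenceUp)
    rej <- vectorRejection(up, da)
    if (vecNorm(rej) < 1e-8) {
        for (axis in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))) {
            rej <- vectorRejection(axis, da)
            if (vecNorm(rej) >= 1e-8) {
                message("reference up parallel to the axial axis; ",
                        "falling back to global axis (",
                        paste(axis, collapse = ","), ")")
                break
            }
        }
    }
    dl0 <- unitVector(rej)
    dl <- as.numeric(rotationAboutAxis(da, roll) %*% dl0)
    de <- crossProduct(da, dl)
    new("ProbePose", rotation = cbind(dl, de, da, deparse.level = 0),
        basePoint = base)
}

#' World sample points of the imaging fan at a pose
#'
#' For each scan-line, depths are uniform in \[0, depth\] inclusive; points
#' are `R (b_i + l v_i) + s`.
#'
#' @param geometry a [ProbeGeometry-class]
#' @param pose a [ProbePose-class]
#' @param samplesPerLine number of depth samples (>= 2)
#' @return list with `points` (n x 3 world mm), `scanline` (index) and
#'   `depth` (mm) vectors; points vary fastest over depth
#' @export
fanPoints <- function(geometry, pose, samplesPerLine) {
    stopifnot(samplesPerLine >= 2)
    sl <- scanlines(geometry)
    depths <- seq(0, geometry@depth, length.out = samplesPerLine)
    n <- geometry@nElements
    idx <- rep(seq_len(n), each = samplesPerLine)
    l <- rep(depths, times = n)
    probePts <- sl$origins[idx, , drop = FALSE] +
        l * sl$directions[idx, , drop = FALSE]
    world <- probePts %*% t(pose@rotation)
    world <- sweep(world, 2, pose@basePoint, "+")
    list(points = world, scanline = idx, depth = l)
}
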