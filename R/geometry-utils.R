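# Small vector / array helpers shared across modules. All internal.

vecNorm <- function(v) sqrt(sum(v^2))

unitVector <- function(v) {
    n <- vecNorm(v)
    if (n < 1e-12) stop("cannot normalise a zero vector")
    v / n
}

crossProduct <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
}

# Component of v orthogonal to the unit vector axis (vector rejection).
vectorRejection <- function(v, axis) v - axis * sum(axis * v)

# Rodrigues rotation matrix about a unit axis by angle (radians).
rotationAboutAxis <- function(axis, angle) {
    a <- unitVector(axis)
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# World coordinates (n x 3) of voxel centres given 0-based index offsets.
voxelToWorld <- function(idx0, spacing, origin, axes) {
    sweep(idx0 %*% diag(spacing) %*% t(axes), 2, origin, "+")
}

# Shift a 3D array by `by` voxels along an axis. `fill` pads the vacated
# slices; fill = NA replicates the edge slice instead (used by the mask
# smoothing so that volume-truncation faces do not create artificial
# gradients).
shiftArray <- function(arr, axis, by, fill = 0) {
    d <- dim(arr)
    replicate <- length(fill) == 1 && is.na(fill)
    out <- array(if (replicate) arr[1] else fill, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) {
        dst[[axis]] <- (1 + by):d[axis]
        src[[axis]] <- 1:(d[axis] - by)
    } else if (by < 0) {
        dst[[axis]] <- 1:(d[axis] + by)
        src[[axis]] <- (1 - by):d[axis]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    if (replicate && by != 0) {
        edge <- src
        pad <- src
        edge[[axis]] <- if (by > 0) 1L else d[axis]
        pad[[axis]] <- if (by > 0) seq_len(by) else
            (d[axis] + by + 1):d[axis]
        out[pad[[1]], pad[[2]], pad[[3]]] <-
            arr[edge[[1]], edge[[2]], edge[[3]]]
    }
    out
}

# Separable Gaussian smoothing in voxel units; borders are edge-replicated.
gaussianSmooth3d <- function(arr, sigmaVox = 1, radius = ceiling(3 * sigmaVox)) {
    w <- dnorm(-radius:radius, sd = sigmaVox)
    w <- w / sum(w)
    out <- arr
    for (axis in 1:3) {
        acc <- array(0, dim(arr))
        for (j in -radius:radius)
            acc <- acc + w[j + radius + 1] * shiftArray(out, axis, j,
                                                        fill = NA)
        out <- acc
    }
    out
}

# One-voxel 6-neighbourhood morphology. Erosion treats out-of-volume as
# foreground so that structures touching the volume border are preserved.
binaryDilate6 <- function(mask) {
    out <- mask
    for (axis in 1:3) for (j in c(-1, 1))
        out <- out | shiftArray(mask, axis, j, fill = FALSE)
    out
}

binaryErode6 <- function(mask) {
    out <- mask
    for (axis in 1:3) for (j in c(-1, 1))
        out <- out & shiftArray(mask, axis, j, fill = TRUE)
    out
}

binaryClose6 <- function(mask) binaryErode6(binaryDilate6(mask))

# Evaluate an expression with a locally seeded RNG, restoring global state.
withLocalSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
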