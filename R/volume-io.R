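# Volume I/O: NIfTI-1 via RNifti, MetaImage (.mhd/.mha) via a plain-text
# header + raw little-endian payload. Geometry is honoured from the headers
# (direction matrix, spacing, origin); intensities pass through unchanged
# except clamping of CT values to [-1024, 4000] HU.

.niftiExt <- "\\.nii(\\.gz)?$"
.metaExt <- "\\.mh[da]$"

#' Read a CT volume
#'
#' Reads a 3D scalar NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mhd`,
#' `.mha`) file into a [CtVolume-class], taking spacing, origin and axis
#' directions from the header. Intensities outside \[-1024, 4000\] HU are
#' clamped with a message.
#'
#' @param path file path
#' @return a [CtVolume-class]
#' @seealso [writeVolume()], [readLabelVolume()]
#' @export
readVolume <- function(path) {
    g <- readVolumeRaw(path)
    ctVolume(g$values, spacing = g$spacing, origin = g$origin, axes = g$axes)
}

#' Read a label volume
#'
#' As [readVolume()] but keeps integer labels unclamped.
#'
#' @param path file path
#' @param labelMap named character vector mapping label ids to names
#' @return a [LabelVolume-class]
#' @export
readLabelVolume <- function(path, labelMap = c("1" = "organ")) {
    g <- readVolumeRaw(path)
    labelVolume(g$values, spacing = g$spacing, origin = g$origin,
                axes = g$axes, labelMap = labelMap)
}

readVolumeRaw <- function(path) {
    if (!file.exists(path))
        stop("cannot read volume: no such file: ", path)
    g <- if (grepl(.niftiExt, path, ignore.case = TRUE)) readNiftiRaw(path)
    else if (grepl(.metaExt, path, ignore.case = TRUE)) readMetaImage(path)
    else stop("unsupported volume format (expect .nii[.gz] or .mhd/.mha): ",
              path)
    if (length(dim(g$values)) != 3)
        stop("expected a 3D image, got ", length(dim(g$values)),
             "D in ", path)
    A <- g$axes
    if (max(abs(crossprod(A) - diag(3))) > 1e-4)
        stop("non-orthogonal direction matrix in ", path)
    # re-orthonormalise small header rounding
    s <- svd(A)
    g$axes <- s$u %*% t(s$v)
    if (det(g$axes) < 0)
        stop("left-handed direction matrix not supported: ", path)
    g
}

readNiftiRaw <- function(path) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    vals <- array(as.vector(vals), dim(vals))  # strip niftiImage class
    if (length(dim(vals)) != 3)
        return(list(values = vals, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    axes = diag(3)))
    M <- RNifti::xform(img)
    L <- M[1:3, 1:3, drop = FALSE]
    spacing <- sqrt(colSums(L^2))
    list(values = vals, spacing = spacing,
         origin = as.numeric(M[1:3, 4]),
         axes = sweep(L, 2, spacing, "/"))
}

#' Write a CT or label volume
#'
#' Writes NIfTI-1 or MetaImage depending on the file extension. CT values
#' are stored as float32 (NIfTI) / MET_FLOAT, labels as int32 / MET_INT so
#' that a round trip preserves the integer type.
#'
#' @param volume a [CtVolume-class] or [LabelVolume-class]
#' @param path output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
    if (!dir.exists(dirname(path)))
        stop("cannot write volume, directory does not exist: ",
             dirname(path))
    isLabel <- is(volume, "LabelVolume")
    vals <- if (isLabel) volume@labels else volume@values
    if (grepl(.niftiExt, path, ignore.case = TRUE)) {
        img <- RNifti::asNifti(vals)
        RNifti::pixdim(img) <- volume@spacing
        M <- diag(4)
        M[1:3, 1:3] <- volume@axes %*% diag(volume@spacing)
        M[1:3, 4] <- volume@origin
        RNifti::qform(img) <- structure(M, code = 2L)
        RNifti::writeNifti(img, path,
                           datatype = if (isLabel) "int32" else "float")
    } else if (grepl(.metaExt, path, ignore.case = TRUE)) {
        writeMetaImage(vals, volume@spacing, volume@origin, volume@axes,
                       path, integerData = isLabel)
    } else {
        stop("unsupported volume format (expect .nii[.gz] or .mhd/.mha): ",
             path)
    }
    invisible(path)
}

# -- MetaImage ---------------------------------------------------------------

.metaTypes <- list(
    MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
    MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
    MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
    MET_INT = list(what = "integer", size = 4, signed = TRUE),
    MET_UINT = list(what = "integer", size = 4, signed = TRUE),
    MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

readMetaImage <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    hdr <- list()
    repeat {
        line <- readLines(con, n = 1, warn = FALSE)
        if (length(line) == 0)
            stop("truncated MetaImage header: ", path)
        kv <- strsplit(line, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
        key <- trimws(kv[1])
        hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
        if (key == "ElementDataFile") break
    }
    ndims <- as.integer(hdr$NDims %||% "3")
    if (ndims != 3) stop("expected a 3D image, got ", ndims, "D in ", path)
    dimSize <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
    spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1",
                                   "\\s+")[[1]])
    origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
    tm <- as.numeric(strsplit(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1",
                              "\\s+")[[1]])
    axes <- matrix(tm, 3, 3, byrow = TRUE)
    if (isTRUE(tolower(hdr$CompressedData %||% "false") == "true"))
        stop("compressed MetaImage payloads are not supported: ", path)
    if (isTRUE(tolower(hdr$BinaryDataByteOrderMSB %||% "false") == "true"))
        stop("big-endian MetaImage payloads are not supported: ", path)
    tp <- .metaTypes[[hdr$ElementType %||% "MET_FLOAT"]]
    if (is.null(tp)) stop("unsupported ElementType: ", hdr$ElementType)
    n <- prod(dimSize)
    dataFile <- hdr$ElementDataFile
    if (identical(dataFile, "LOCAL")) {
        raw <- readBin(con, tp$what, n = n, size = tp$size,
                       signed = tp$signed, endian = "little")
    } else {
        con2 <- file(file.path(dirname(path), dataFile), "rb")
        on.exit(close(con2), add = TRUE)
        raw <- readBin(con2, tp$what, n = n, size = tp$size,
                       signed = tp$signed, endian = "little")
    }
    if (length(raw) != n) stop("truncated MetaImage payload: ", path)
    list(values = array(raw, dimSize), spacing = spacing, origin = origin,
         axes = axes)
}

writeMetaImage <- function(vals, spacing, origin, axes, path,
                           integerData = FALSE) {
    local <- grepl("\\.mha$", path, ignore.case = TRUE)
    dataFile <- if (local) "LOCAL"
    else sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(
        "ObjectType = Image",
        "NDims = 3",
        "BinaryData = True",
        "BinaryDataByteOrderMSB = False",
        "CompressedData = False",
        paste("TransformMatrix =", paste(format(t(axes), trim = TRUE,
                                                digits = 17), collapse = " ")),
        paste("Offset =", paste(format(origin, trim = TRUE, digits = 17),
                                collapse = " ")),
        paste("ElementSpacing =", paste(format(spacing, trim = TRUE,
                                               digits = 17), collapse = " ")),
        paste("DimSize =", paste(dim(vals), collapse = " ")),
        paste("ElementType =", if (integerData) "MET_INT" else "MET_DOUBLE"),
        paste("ElementDataFile =", dataFile))
    payload <- if (integerData) as.integer(vals) else as.numeric(vals)
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    if (local) {
        writeBin(payload, con, size = if (integerData) 4L else 8L,
                 endian = "little")
    } else {
        con2 <- file(file.path(dirname(path), dataFile), "wb")
        on.exit(close(con2), add = TRUE)
        writeBin(payload, con2, size = if (integerData) 4L else 8L,
                 endian = "little")
    }
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- Sampling ----------------------------------------------------------------

#' Trilinear sampling of a volume at world points
#'
#' Samples the volume at arbitrary world positions (mm) by trilinear
#' interpolation; positions outside the grid return `outside` (air by
#' default), so rays may legitimately start at the skin or clip the volume
#' boundary.
#'
#' @param volume a [CtVolume-class] (or [AttenuationField-class])
#' @param points n x 3 matrix (or length-3 vector) of world positions in mm
#' @param outside value returned outside the grid (default -1024 HU)
#' @return numeric vector of sampled values
#' @examples
#' v <- ctVolume(array(rep(0:7, each = 16), c(4, 4, 8)))
#' sampleTrilinear(v, c(0.5, 0.5, 2.5))
#' @export
sampleTrilinear <- function(volume, points, outside = -1024) {
    sampleVolume(volume, points, outside = outside, mode = 1L)
}

# mode 0 = nearest voxel, 1 = trilinear
sampleVolume <- function(volume, points, outside, mode = 1L) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 3)
    vals <- if (is(volume, "AttenuationField")) volume@mu
    else if (is(volume, "LabelVolume")) volume@labels
    else volume@values
    storage.mode(vals) <- "double"
    sampleVolumeCpp(as.numeric(vals), dim(vals), volume@spacing,
                    volume@origin, volume@axes,
                    points, outside, as.integer(mode))
}
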