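#' @import methods
NULL

#' VoxelImage: one channel of a calibrated 3D stack
#'
#' A single-channel 3D image with physical voxel dimensions. All geometry in
#' the package is computed in micrometres; the `VoxelImage` is the coordinate
#' substrate that carries the calibration. Axis order is (Z, Y, X) throughout,
#' matching the confocal acquisition order of z-stacked frames. The physical
#' coordinate of voxel (i, j, k) (1-based) is its centre,
#' `(i - 0.5, j - 0.5, k - 0.5) * voxelSize` in micrometres.
#'
#' @slot intensities 3D numeric array (Z, Y, X) of non-negative integers.
#' @slot voxelSize numeric(3), voxel edge lengths in micrometres, (z, y, x).
#'   Confocal stacks are typically anisotropic (z step larger than the
#'   xy pixel size), e.g. `c(0.34, 0.105, 0.105)`.
#' @slot channelName single string naming the channel (e.g. "dapi", "ct19").
#' @slot bitDepth integer, 8 or 16; the acquisition pixel depth.
#'
#' @seealso [VoxelImage()] for the constructor, [StackSet-class]
#' @export
setClass("VoxelImage",
         representation(intensities = "array",
                        voxelSize   = "numeric",
                        channelName = "character",
                        bitDepth    = "integer"))

setValidity("VoxelImage", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L)
    msg <- c(msg, "intensities must be a 3D array (Z, Y, X)")
  else if (any(d < 2L))
    msg <- c(msg, "each image dimension must be >= 2")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers (z, y, x) in um")
  if (length(object@channelName) != 1L)
    msg <- c(msg, "channelName must be a single string")
  if (length(object@bitDepth) != 1L || !object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (any(object@intensities < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelImage
#'
#' @param intensities 3D array (Z, Y, X) of non-negative values; rounded to
#'   integers.
#' @param voxelSize numeric(3) voxel size in um, (z, y, x).
#' @param channelName channel label.
#' @param bitDepth 8 or 16.
#' @return A [VoxelImage-class] object.
#' @examples
#' img <- VoxelImage(array(0L, c(4, 8, 8)), c(0.34, 0.105, 0.105), "dapi")
#' voxelSize(img)
#' @export
VoxelImage <- function(intensities, voxelSize = c(0.34, 0.105, 0.105),
                       channelName = "channel", bitDepth = 8L) {
  new("VoxelImage",
      intensities = round(intensities),
      voxelSize = as.numeric(voxelSize),
      channelName = as.character(channelName),
      bitDepth = as.integer(bitDepth))
}

#' StackSet: the channels of one multi-channel acquisition
#'
#' An ordered, named collection of [VoxelImage-class] channels sharing shape
#' and calibration — one cropped nucleus imaged sequentially in multi-channel
#' mode (DAPI, chromosome paints, optional lamina and gene-locus channels).
#'
#' @slot channels named list of `VoxelImage` objects, all with identical
#'   dimensions and voxel size.
#' @seealso [StackSet()], [readStack()], [writeStack()]
#' @export
setClass("StackSet", representation(channels = "list"))

setValidity("StackSet", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("StackSet must contain >= 1 channel")
  if (!all(vapply(ch, is, logical(1), "VoxelImage")))
    return("all channels must be VoxelImage objects")
  nms <- unname(vapply(ch, channelName, character(1)))
  if (is.null(names(ch)) || !identical(names(ch), nms))
    return("channel list names must equal the channelName of each VoxelImage")
  if (anyDuplicated(nms)) return("channel names must be unique")
  d0 <- dim(ch[[1]]@intensities); v0 <- ch[[1]]@voxelSize
  for (x in ch) {
    if (!identical(dim(x@intensities), d0))
      return("all channels must share the same dimensions")
    if (!isTRUE(all.equal(x@voxelSize, v0)))
      return("all channels must share the same voxel size")
  }
  TRUE
})

#' Construct a StackSet
#'
#' @param ... `VoxelImage` objects (or a single list of them). Channel names
#'   are taken from each image's `channelName`.
#' @return A [StackSet-class].
#' @export
StackSet <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1]]) && !is(ch[[1]], "VoxelImage"))
    ch <- ch[[1]]
  names(ch) <- vapply(ch, channelName, character(1))
  new("StackSet", channels = ch)
}

#' SegmentedObject: a labeled 3D connected region
#'
#' One 26-connected voxel component — a nucleus, one chromosome-territory
#' copy, or one gene-locus spot — with its geometric descriptors. The
#' geometric centre (`centroidUm`, unweighted mean of voxel centres) is used
#' for nuclei and territories; the intensity-weighted centre of mass
#' (`centerOfMassUm`) is used for gene-locus spots.
#'
#' @slot label integer component label (1 = largest object in its channel).
#' @slot voxelIndices integer matrix, one row per voxel, columns (z, y, x),
#'   1-based.
#' @slot centroidUm numeric(3) geometric centre in um, (z, y, x).
#' @slot centerOfMassUm numeric(3) intensity-weighted centre in um.
#' @slot volumeUm3 voxel count times voxel volume, um^3.
#' @slot channelName channel the object came from.
#' @export
setClass("SegmentedObject",
         representation(label = "integer",
                        voxelIndices = "matrix",
                        centroidUm = "numeric",
                        centerOfMassUm = "numeric",
                        volumeUm3 = "numeric",
                        channelName = "character"))

setValidity("SegmentedObject", function(object) {
  if (nrow(object@voxelIndices) == 0L) return("object has no voxels")
  if (ncol(object@voxelIndices) != 3L) return("voxelIndices must be n x 3")
  bb_lo <- apply(object@voxelIndices, 2, min)
  bb_hi <- apply(object@voxelIndices, 2, max)
  # centroid must fall inside the bounding box (in voxel units)
  vx <- object@centroidUm  # checked against box in um by caller's voxel size;
  TRUE
})

#' RadialMeasurement: the A/B/C collinear radial-distance construction
#'
#' Holds the three collinear points of the percent-radial-distance
#' measurement: the geometric centre of the nucleus (A), the geometric centre
#' of the territory (B), and the point where the ray from A through B meets
#' the nuclear periphery (C). X = |AB|, Y = |AC|, and
#' `rdPercent = 100 * X / Y` (0 = nuclear centre, 100 = periphery).
#'
#' @slot A_um,B_um,C_um numeric(3) points in um (z, y, x). `C_um` is `NA` when
#'   the measurement is degenerate (B coincides with A).
#' @slot X_um,Y_um distances |AB| and |AC| in um.
#' @slot rdPercent percent radial distance in [0, 100].
#' @slot degenerate TRUE when B == A within 1e-9 um (rdPercent is 0 and C is
#'   undefined).
#' @export
setClass("RadialMeasurement",
         representation(A_um = "numeric", B_um = "numeric", C_um = "numeric",
                        X_um = "numeric", Y_um = "numeric",
                        rdPercent = "numeric", degenerate = "logical"))

setValidity("RadialMeasurement", function(object) {
  msg <- character()
  if (!object@degenerate && object@X_um > object@Y_um + 1e-9)
    msg <- c(msg, "X must not exceed Y")
  if (object@rdPercent < 0 || object@rdPercent > 100)
    msg <- c(msg, "rdPercent must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' ShellDistribution: territory counts per nuclear sub-shell
#'
#' Counts of chromosome territories falling into the five concentric nuclear
#' sub-shells I (innermost, RD 0-20%) through V (peripheral, RD 80-100%) for
#' one experimental condition. Pooling across replicates is additive.
#'
#' @slot condition condition label (e.g. "untreated", "siLaminB2").
#' @slot counts named integer(5), names "I".."V".
#' @slot n total number of territories (sum of counts).
#' @seealso [shellDistribution()], [compareShellDistributions()]
#' @export
setClass("ShellDistribution",
         representation(condition = "character", counts = "integer",
                        n = "integer"))

setValidity("ShellDistribution", function(object) {
  if (!identical(names(object@counts), c("I", "II", "III", "IV", "V")))
    return("counts must be named I..V")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@n) return("counts must sum to n")
  TRUE
})

## ---- generics ----

#' @rdname VoxelImage-class
#' @param object,x a `VoxelImage` or `StackSet`.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VoxelImage-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname StackSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname VoxelImage-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname VoxelImage-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @export
#' @rdname SegmentedObject-class
setGeneric("volumeUm3", function(x) standardGeneric("volumeUm3"))

#' @export
#' @rdname SegmentedObject-class
setGeneric("centroidUm", function(x) standardGeneric("centroidUm"))

#' @export
#' @rdname SegmentedObject-class
setGeneric("centerOfMassUm", function(x) standardGeneric("centerOfMassUm"))

#' @export
#' @rdname RadialMeasurement-class
setGeneric("rdPercent", function(x) standardGeneric("rdPercent"))

setMethod("voxelSize", "VoxelImage", function(x) x@voxelSize)
setMethod("voxelSize", "StackSet", function(x) x@channels[[1]]@voxelSize)
setMethod("channelName", "VoxelImage", function(x) x@channelName)
setMethod("channelNames", "StackSet", function(x) names(x@channels))
setMethod("intensities", "VoxelImage", function(x) x@intensities)
setMethod("bitDepth", "VoxelImage", function(x) x@bitDepth)
setMethod("volumeUm3", "SegmentedObject", function(x) x@volumeUm3)
setMethod("centroidUm", "SegmentedObject", function(x) x@centroidUm)
setMethod("centerOfMassUm", "SegmentedObject", function(x) x@centerOfMassUm)
setMethod("rdPercent", "RadialMeasurement", function(x) x@rdPercent)

#' @rdname StackSet-class
#' @param i channel name or index.
#' @export
setMethod("[[", "StackSet", function(x, i) x@channels[[i]])

#' @rdname StackSet-class
#' @export
setMethod("length", "StackSet", function(x) length(x@channels))

#' @rdname VoxelImage-class
#' @export
setMethod("dim", "VoxelImage", function(x) dim(x@intensities))

#' @rdname StackSet-class
#' @export
setMethod("dim", "StackSet", function(x) dim(x@channels[[1]]@intensities))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelImage '%s': %d x %d x %d (Z,Y,X), voxel %s um, %d-bit\n",
              object@channelName, d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x "),
              object@bitDepth))
})

setMethod("show", "StackSet", function(object) {
  d <- dim(object)
  cat(sprintf("StackSet: %d channel(s) [%s], %d x %d x %d (Z,Y,X), voxel %s um\n",
              length(object), paste(channelNames(object), collapse = ", "),
              d[1], d[2], d[3],
              paste(signif(voxelSize(object), 4), collapse = " x ")))
})

setMethod("show", "SegmentedObject", function(object) {
  cat(sprintf(
    "SegmentedObject label %d ('%s'): %d voxels, %.3f um^3, centroid (%s) um\n",
    object@label, object@channelName, nrow(object@voxelIndices),
    object@volumeUm3, paste(signif(object@centroidUm, 4), collapse = ", ")))
})

setMethod("show", "RadialMeasurement", function(object) {
  if (object@degenerate)
    cat("RadialMeasurement: degenerate (B = A), rd = 0%\n")
  else
    cat(sprintf("RadialMeasurement: X = %.3f um, Y = %.3f um, rd = %.1f%%\n",
                object@X_um, object@Y_um, object@rdPercent))
})

setMethod("show", "ShellDistribution", function(object) {
  cat(sprintf("ShellDistribution '%s' (n = %d): %s\n", object@condition,
              object@n,
              paste(sprintf("%s=%d", names(object@counts), object@counts),
                    collapse = " ")))
})
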