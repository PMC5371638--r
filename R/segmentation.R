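# Segmentation: channel -> labeled 3D objects with centroids, centres of
# mass and volumes. 26-connectivity in 3D; objects below a voxel-count floor
# (default 50, to suppress hybridization speckle) are discarded.

#' Threshold a channel into a binary mask
#'
#' @param img a [VoxelImage-class].
#' @param method `"otsu"` (default; Otsu's histogram threshold computed by
#'   `EBImage::otsu`) or `"fixed"`.
#' @param value threshold for `method = "fixed"`; the comparison is
#'   inclusive (`intensity >= value` is foreground).
#' @return logical 3D array of the same shape.
#' @examples
#' img <- VoxelImage(array(c(0, 200), c(4, 4, 4)), channelName = "x")
#' sum(thresholdChannel(img, "fixed", value = 100))
#' @export
thresholdChannel <- function(img, method = c("otsu", "fixed"), value = NULL) {
  stopifnot(is(img, "VoxelImage"))
  method <- match.arg(method)
  arr <- intensities(img)
  if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' requires a threshold value")
    return(arr >= value)
  }
  maxval <- 2^bitDepth(img) - 1
  if (min(arr) == max(arr))
    stop("constant image: Otsu threshold undefined; use method = 'fixed'")
  th <- EBImage::otsu(EBImage::Image(as.numeric(arr) / maxval,
                                     dim = c(length(arr), 1L)),
                      range = c(0, 1), levels = maxval + 1)
  arr > th * maxval
}

.makeSegmentedObject <- function(idx, label, voxelSize, intensityArr,
                                 channelName) {
  P <- .voxelToUm(idx, voxelSize)
  centroid <- colMeans(P)
  if (is.null(intensityArr)) {
    cm <- centroid
  } else {
    w <- as.numeric(intensityArr[idx])
    cm <- if (sum(w) > 0) colSums(P * w) / sum(w) else centroid
  }
  new("SegmentedObject", label = as.integer(label),
      voxelIndices = idx, centroidUm = centroid, centerOfMassUm = cm,
      volumeUm3 = nrow(idx) * prod(voxelSize),
      channelName = channelName)
}

#' Label 26-connected 3D objects in a binary mask
#'
#' Components with at least `minVoxels` voxels are returned as
#' [SegmentedObject-class]s, ordered by decreasing size; ties broken by the
#' smallest (z, y, x) of each component's minimum voxel index. When an
#' intensity image is supplied, the intensity-weighted centre of mass is
#' computed from it; otherwise it equals the geometric centroid.
#'
#' @param mask logical 3D array.
#' @param voxelSize numeric(3) um (z, y, x); taken from `img` when given.
#' @param img optional [VoxelImage-class] supplying intensities (and
#'   calibration) for centre-of-mass weighting.
#' @param minVoxels minimum component size in voxels (default 50).
#' @param channelName label recorded on each object.
#' @return list of `SegmentedObject` (possibly empty).
#' @export
labelObjects <- function(mask, voxelSize = NULL, img = NULL, minVoxels = 50L,
                         channelName = "") {
  if (!is.null(img)) {
    stopifnot(is(img, "VoxelImage"))
    if (is.null(voxelSize)) voxelSize <- voxelSize(img)
    if (!nzchar(channelName)) channelName <- channelName(img)
    intensityArr <- intensities(img)
  } else intensityArr <- NULL
  if (is.null(voxelSize)) stop("voxelSize (or img) must be supplied")
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- .labelComponents(mask, connectivity = 26L)
  if (all(lab == 0L)) return(list())
  tab <- tabulate(lab)
  keep <- which(tab >= minVoxels)
  if (length(keep) == 0L) return(list())
  d <- dim(mask)
  fg <- which(lab > 0L)
  z <- ((fg - 1L) %% d[1]) + 1L
  y <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  memb <- lab[fg]
  # deterministic ordering: decreasing size, ties by lexicographic minimum
  # (z, y, x) voxel of the component
  ord <- order(memb)
  minIdx <- vapply(keep, function(k) {
    rows <- which(memb == k)
    key <- (z[rows] - 1) * d[2] * d[3] + (y[rows] - 1) * d[3] + (x[rows] - 1)
    min(key)
  }, numeric(1))
  keep <- keep[order(-tab[keep], minIdx)]
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    rows <- which(memb == keep[i])
    idx <- cbind(z = z[rows], y = y[rows], x = x[rows])
    out[[i]] <- .makeSegmentedObject(idx, i, voxelSize, intensityArr,
                                     channelName)
  }
  out
}

#' Extract the nucleus from a binary mask
#'
#' The largest 26-connected component, with internal cavities filled in 3D
#' (background regions not connected to the image border become foreground)
#' before the centroid and volume are measured — the geometric centre of the
#' nucleus must describe the solid body, not a shell.
#'
#' @param mask logical 3D array from thresholding the nuclear stain.
#' @param voxelSize numeric(3) um (z, y, x).
#' @param img optional [VoxelImage-class] (supplies calibration and
#'   intensities).
#' @return a [SegmentedObject-class].
#' @export
nucleusObject <- function(mask, voxelSize = NULL, img = NULL) {
  if (!is.null(img) && is.null(voxelSize)) voxelSize <- voxelSize(img)
  if (is.null(voxelSize)) stop("voxelSize (or img) must be supplied")
  if (!any(mask)) stop("empty mask: no nucleus found")
  filled <- .fillHoles3D(mask)
  objs <- labelObjects(filled, voxelSize = voxelSize, img = img,
                       minVoxels = 1L, channelName = "nucleus")
  objs[[1]]
}

#' Binary mask of one segmented object
#'
#' @param object a [SegmentedObject-class].
#' @param dims integer(3) array dimensions (Z, Y, X).
#' @return logical array with the object's voxels TRUE.
#' @export
objectMask <- function(object, dims) {
  m <- array(FALSE, dims)
  m[object@voxelIndices] <- TRUE
  m
}

#' Tabulate segmented objects
#'
#' One row per object: label, voxel count, volume, centroid and centre of
#' mass in um.
#'
#' @param objects list of [SegmentedObject-class].
#' @param imageId identifier recorded in the first column.
#' @return data.frame.
#' @export
objectsTable <- function(objects, imageId = "") {
  if (length(objects) == 0L)
    return(data.frame(image_id = character(), channel = character(),
                      label = integer(), n_voxels = integer(),
                      volume_um3 = numeric(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(), cm_z = numeric(),
                      cm_y = numeric(), cm_x = numeric()))
  do.call(rbind, lapply(objects, function(o) {
    data.frame(image_id = imageId, channel = o@channelName, label = o@label,
               n_voxels = nrow(o@voxelIndices), volume_um3 = o@volumeUm3,
               centroid_z = o@centroidUm[1], centroid_y = o@centroidUm[2],
               centroid_x = o@centroidUm[3], cm_z = o@centerOfMassUm[1],
               cm_y = o@centerOfMassUm[2], cm_x = o@centerOfMassUm[3])
  }))
}
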