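# Reading and writing the artifacts the pipeline touches: multi-channel TIFF
# z-stacks with physical calibration, TSV gene-expression and chromosome
# annotation tables, and JSON ground-truth sidecars.
#
# TIFF layout: pages ordered channel-major (all z planes of channel 1, then
# channel 2, ...) — i.e. axes C, Z, Y, X. Calibration and channel names
# travel in a JSON sidecar (<path>.json) written next to the TIFF; on read,
# ImageJ-style description tags ("spacing=", "images=", "channels=") and
# x/y-resolution tags are also understood when no sidecar is present.

#' Write a StackSet as a multi-channel TIFF z-stack
#'
#' Pages are written channel-major (C, Z, Y, X). Integer intensities and the
#' acquisition bit depth are preserved exactly. A JSON sidecar
#' (`<path>.json`) records voxel size, channel names and bit depth so that
#' [readStack()] round-trips the calibration.
#'
#' @param stacks a [StackSet-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stacks, path) {
  stopifnot(is(stacks, "StackSet"))
  bits <- bitDepth(stacks[[1]])
  maxval <- 2^bits - 1
  pages <- list()
  for (nm in channelNames(stacks)) {
    arr <- intensities(stacks[[nm]])
    for (z in seq_len(dim(arr)[1]))
      pages[[length(pages) + 1L]] <- arr[z, , ] / maxval
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "deflate", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to '", path, "'")
  meta <- list(voxel_size_um = voxelSize(stacks),
               channels = channelNames(stacks),
               bit_depth = bits,
               axes = "CZYX")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.parseImageJDescription <- function(desc) {
  out <- list()
  if (is.null(desc) || !nzchar(desc)) return(out)
  for (key in c("spacing", "channels", "slices", "images")) {
    m <- regmatches(desc, regexec(paste0(key, "=([0-9.eE+-]+)"), desc))[[1]]
    if (length(m) == 2) out[[key]] <- as.numeric(m[2])
  }
  out
}

#' Read a multi-channel TIFF z-stack into a StackSet
#'
#' Calibration is taken from, in order of preference: the JSON sidecar
#' written by [writeStack()]; ImageJ-style metadata in the TIFF (description
#' `spacing=` for the z step, x-resolution tag for the pixel size); the
#' `defaultVoxelSize` argument, in which case a warning is issued.
#'
#' @param path TIFF path.
#' @param nChannels number of channels; taken from metadata when available,
#'   defaulting to 1. Page count must be divisible by it.
#' @param defaultVoxelSize calibration (um, z/y/x) applied when the file
#'   carries none.
#' @param channelNames optional channel names overriding metadata.
#' @return A [StackSet-class].
#' @export
readStack <- function(path, nChannels = NULL,
                      defaultVoxelSize = c(0.34, 0.105, 0.105),
                      channelNames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("format error: expected single-sample (grayscale) pages")
  dims2 <- unique(lapply(pages, dim))
  if (length(dims2) != 1L)
    stop("format error: pages have mismatched shapes")
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ij <- .parseImageJDescription(attr(pages[[1]], "description"))

  vs <- NULL
  if (!is.null(meta$voxel_size_um)) {
    vs <- as.numeric(meta$voxel_size_um)
  } else if (!is.null(ij$spacing)) {
    xres <- attr(pages[[1]], "x.resolution")
    pix <- if (!is.null(xres) && xres > 0) 1 / xres else NA_real_
    if (is.finite(pix)) vs <- c(ij$spacing, pix, pix)
  }
  if (is.null(vs)) {
    vs <- as.numeric(defaultVoxelSize)
    warning("no voxel-size metadata in '", path, "'; using default ",
            paste(vs, collapse = " x "), " um")
  }

  if (is.null(nChannels)) {
    nChannels <- if (!is.null(meta$channels)) length(meta$channels)
                 else if (!is.null(ij$channels)) as.integer(ij$channels)
                 else 1L
  }
  nChannels <- as.integer(nChannels)
  if (length(pages) %% nChannels != 0L)
    stop("format error: ", length(pages), " pages not divisible by ",
         nChannels, " channels")
  nz <- length(pages) %/% nChannels
  if (nz < 2L)
    stop("format error: stack must be 3D (>= 2 z planes per channel)")

  nms <- channelNames
  if (is.null(nms)) {
    nms <- if (!is.null(meta$channels)) as.character(meta$channels)
           else paste0("channel", seq_len(nChannels))
  }
  if (length(nms) != nChannels)
    stop("channel name count does not match channel count")

  d2 <- dims2[[1]]
  imgs <- lapply(seq_len(nChannels), function(ci) {
    arr <- array(0L, c(nz, d2[1], d2[2]))
    for (z in seq_len(nz))
      arr[z, , ] <- pages[[(ci - 1L) * nz + z]]
    VoxelImage(arr, vs, nms[ci], as.integer(bits))
  })
  StackSet(imgs)
}

.readCheckedTSV <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("parse error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  tab
}

.numericColumn <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop("parse error in '", path, "': non-numeric ", name, " at row ",
         bad[1])
  out
}

#' Read a per-gene expression table
#'
#' Expects a TSV with header `gene_id, chromosome, fold_change, p_value`
#' (fold change signed and linear). Chromosome labels are normalized to the
#' canonical set 1-22, X, Y.
#'
#' @param path TSV path.
#' @return data.frame of gene records.
#' @export
readGeneTable <- function(path) {
  tab <- .readCheckedTSV(path, c("gene_id", "chromosome", "fold_change",
                                 "p_value"))
  fc <- .numericColumn(tab$fold_change, "fold_change", path)
  p <- .numericColumn(tab$p_value, "p_value", path)
  if (any(fc == 0))
    stop("parse error in '", path, "': fold_change of 0 at row ",
         which(fc == 0)[1])
  if (any(p < 0 | p > 1))
    stop("parse error in '", path, "': p_value outside [0, 1] at row ",
         which(p < 0 | p > 1)[1])
  data.frame(gene_id = tab$gene_id,
             chromosome = normalizeChromosome(tab$chromosome),
             fold_change = fc, p_value = p)
}

#' Read a chromosome annotation table
#'
#' Expects a TSV with header `chromosome, coding_genes, length_mbp`. Gene
#' density (genes/Mbp) is computed as `coding_genes / length_mbp`.
#'
#' @param path TSV path.
#' @return data.frame with columns `chromosome`, `coding_genes`,
#'   `length_mbp`, `gene_density`.
#' @export
readAnnotation <- function(path) {
  tab <- .readCheckedTSV(path, c("chromosome", "coding_genes", "length_mbp"))
  cg <- .numericColumn(tab$coding_genes, "coding_genes", path)
  ln <- .numericColumn(tab$length_mbp, "length_mbp", path)
  if (any(cg <= 0) || any(ln <= 0))
    stop("parse error in '", path,
         "': coding_genes and length_mbp must be positive")
  data.frame(chromosome = normalizeChromosome(tab$chromosome),
             coding_genes = as.integer(cg), length_mbp = ln,
             gene_density = cg / ln)
}

#' Write / read a ground-truth sidecar
#'
#' Serializes the ground-truth record produced by [simulateCell()] as JSON.
#'
#' @param truth ground-truth list.
#' @param path JSON path.
#' @return `path` (write) or the ground-truth list (read).
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("territories", "loci"))
    if (!is.null(out[[f]])) out[[f]] <- as.data.frame(out[[f]])
  out
}
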