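# Internal geometry and array helpers. All physical coordinates are voxel
# centres in micrometres, axis order (z, y, x), 1-based voxel indices.

# voxel index matrix (n x 3) -> um coordinates of voxel centres
.voxelToUm <- function(idx, voxelSize) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(idx - 0.5, 2, voxelSize, "*")
}

# um point -> containing voxel index (1-based); may fall outside the array
.umToVoxel <- function(um, voxelSize) {
  if (is.matrix(um)) floor(sweep(um, 2, voxelSize, "/")) + 1L
  else floor(um / voxelSize) + 1L
}

# is a um point inside a logical mask (FALSE when outside array bounds)
.insideMask <- function(um, mask, voxelSize) {
  d <- dim(mask)
  v <- .umToVoxel(um, voxelSize)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  ok <- v[, 1] >= 1 & v[, 1] <= d[1] & v[, 2] >= 1 & v[, 2] <= d[2] &
    v[, 3] >= 1 & v[, 3] <= d[3]
  out <- rep(FALSE, nrow(v))
  if (any(ok)) out[ok] <- mask[cbind(v[ok, 1], v[ok, 2], v[ok, 3])]
  out
}

# ZYX rotation matrix from Euler angles (radians): R = Rz(a) %*% Ry(b) %*% Rx(c)
# applied to (x, y, z) column vectors in um space.
.eulerRotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# 26- or 6-connected components of TRUE voxels in a 3D logical array.
# Returns an integer array of labels (0 = background), labels in arbitrary
# order; use .orderComponents for the deterministic ordering.
.labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  nzy <- d[1] * d[2]
  # neighbour offsets: half-space only (each undirected edge counted once)
  if (connectivity == 26L) {
    offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
                   (offs$dx == 0 & offs$dy == 0 & offs$dz > 0), ]
  } else {
    offs <- data.frame(dz = c(1, 0, 0), dy = c(0, 1, 0), dx = c(0, 0, 1))
  }
  # array index components of foreground voxels
  z <- ((fg - 1L) %% d[1]) + 1L
  y <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((fg - 1L) %/% nzy) + 1L
  node <- seq_along(fg)          # node ids in the graph
  pos <- integer(prod(d))        # linear index -> node id (0 = background)
  pos[fg] <- node
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    zz <- z + offs$dz[r]; yy <- y + offs$dy[r]; xx <- x + offs$dx[r]
    ok <- zz >= 1L & zz <= d[1] & yy >= 1L & yy <= d[2] & xx >= 1L & xx <= d[3]
    if (!any(ok)) next
    nb <- (xx[ok] - 1L) * nzy + (yy[ok] - 1L) * d[1] + zz[ok]
    nbnode <- pos[nb]
    hit <- nbnode > 0L
    if (any(hit)) {
      from <- c(from, node[ok][hit])
      to <- c(to, nbnode[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

# Fill cavities: background voxels not 6-connected to the array border become
# foreground. Operates in 3D, so slice holes and enclosed 3D voids both fill.
.fillHoles3D <- function(mask) {
  bg <- !mask
  lab <- .labelComponents(bg, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  hole <- bg & !(array(lab %in% border, d))
  mask | hole
}

# Separable Gaussian blur of a 3D array with per-axis sigma given in um;
# sigma is converted to voxel units via voxelSize. sigma = 0 on an axis skips
# that axis. Zero padding at the borders.
.gaussianBlur3D <- function(arr, sigmaUm, voxelSize) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaUm[ax] / voxelSize[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    out <- array(0, d)
    for (k in seq(-r, r)) {
      wt <- w[k + r + 1]
      src <- .shiftAxis(arr, ax, k)
      out <- out + wt * src
    }
    arr <- out
  }
  arr
}

# shift a 3D array by k along axis ax, zero-filling
.shiftAxis <- function(arr, ax, k) {
  if (k == 0L) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  n <- d[ax]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  idx_src <- list(1:d[1], 1:d[2], 1:d[3]); idx_dst <- idx_src
  idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Normalize chromosome labels to the canonical set
#'
#' Maps free-form chromosome labels ("chr19", " 19", "x") onto the canonical
#' human set `1..22, X, Y`.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @examples
#' normalizeChromosome(c("chr19", "X", "chrx"))
#' @export
normalizeChromosome <- function(x) {
  out <- toupper(trimws(as.character(x)))
  out <- sub("^CHR", "", out)
  out <- sub("^0+(?=[0-9])", "", out, perl = TRUE)
  valid <- c(as.character(1:22), "X", "Y")
  bad <- !out %in% valid
  if (any(bad))
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  out
}

# quantile-based median / IQR with linear interpolation (type 7)
.medianIQR <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], IQR = q[3] - q[1])
}
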