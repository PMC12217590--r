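# Image frontend: tessellate frames into pixel blocks, concatenate colour and
# time (R frames per voxel), reduce each block with an SVD basis, and quantize
# the singular variates on a uniform, zero-centred, odd-count grid.

# Coerce frames to a [H, W, C, T] array.
asFrameArray <- function(frames) {
  d <- dim(frames)
  if (is.null(d) || length(d) < 2L) stop("frames must be an array")
  if (length(d) == 2L) dim(frames) <- c(d, 1L, 1L)
  if (length(dim(frames)) == 3L) {
    d <- dim(frames)
    dim(frames) <- c(d[1L], d[2L], 1L, d[3L])  # greyscale stack
  }
  frames
}

#' Fit a block partition to an image stack
#'
#' Deterministic row-major tiling of the frame into non-overlapping blocks;
#' fails rather than pads when the image is not divisible by the block (or the
#' frame count by \code{R}).
#'
#' @param frames array (H x W x C x T, or H x W x T greyscale).
#' @param blockShape integer(2): block height, width in pixels.
#' @param R frames per time-colour-pixel voxel.
#' @return a \linkS4class{BlockPartition}.
#' @export
fitPartition <- function(frames, blockShape, R = 1L) {
  frames <- asFrameArray(frames)
  d <- dim(frames)
  blockShape <- as.integer(blockShape)
  R <- as.integer(R)
  if (d[1L] %% blockShape[1L] != 0L || d[2L] %% blockShape[2L] != 0L)
    stop("image dimensions must be divisible by the block dimensions")
  if (d[4L] %% R != 0L)
    stop("frame count must be divisible by R")
  nbr <- d[1L] %/% blockShape[1L]
  nbc <- d[2L] %/% blockShape[2L]
  # row-major over blocks: group index runs along block columns first
  cent <- matrix(0, nbr * nbc, 2L)
  g <- 0L
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    g <- g + 1L
    cent[g, ] <- c((bi - 0.5) * blockShape[1L] + 0.5,
                   (bj - 0.5) * blockShape[2L] + 0.5)
  }
  new("BlockPartition", imageShape = d[1:3], blockShape = blockShape,
      R = R, centroids = cent)
}

#' Number of groups in a partition
#' @param partition a BlockPartition
#' @export
nGroups <- function(partition) nrow(partition@centroids)

# Pixel (row, col) index sets for group g.
groupPixels <- function(partition, g) {
  nbc <- partition@imageShape[2L] %/% partition@blockShape[2L]
  bi <- (g - 1L) %/% nbc
  bj <- (g - 1L) %% nbc
  list(rows = bi * partition@blockShape[1L] + seq_len(partition@blockShape[1L]),
       cols = bj * partition@blockShape[2L] + seq_len(partition@blockShape[2L]))
}

# Training matrix for group g: one column per voxel step, rows concatenate
# (pixel row, pixel col, channel, frame-within-voxel).
blockMatrix <- function(frames, partition, g) {
  frames <- asFrameArray(frames)
  px <- groupPixels(partition, g)
  R <- partition@R
  Tn <- dim(frames)[4L] %/% R
  d <- prod(partition@blockShape) * partition@imageShape[3L] * R
  out <- matrix(0, d, Tn)
  for (t in seq_len(Tn)) {
    fr <- frames[px$rows, px$cols, , ((t - 1L) * R + 1L):(t * R), drop = FALSE]
    out[, t] <- as.vector(fr)
  }
  out
}

#' Fit a group codec from stacked training vectors
#'
#' Retains at most \code{maxVectors} left singular vectors whose relative
#' singular value exceeds \code{retention}; constant blocks retain none (the
#' block is then represented by a single discrete symbol). Quantization bins
#' are uniform with an odd number of levels so zero is always a bin centre;
#' bins span the +/- maximum absolute training variate per component.
#'
#' @param x matrix (blockDim x nSamples) of training vectors for one group.
#' @param maxVectors cap on retained components.
#' @param nLevels odd number of quantization levels per variate.
#' @param retention relative singular-value cutoff (S_i/S_1 > retention).
#' @return a \linkS4class{GroupCodec}.
#' @export
fitCodec <- function(x, maxVectors = 16L, nLevels = 7L, retention = 1 / 64) {
  if (!is.matrix(x) || ncol(x) < 1L) stop("empty training set")
  if (nLevels %% 2L == 0L) stop("nLevels must be odd")
  mu <- rowMeans(x)
  xc <- x - mu
  if (max(abs(xc)) < 1e-12) {
    return(new("GroupCodec", basis = matrix(0, nrow(x), 0L),
               singularValues = numeric(0), nLevels = as.integer(nLevels),
               binCenters = list(), mean = mu))
  }
  sv <- svd(xc, nu = min(dim(xc)), nv = 0L)
  keep <- which(sv$d > retention * sv$d[1L] & sv$d > 1e-10)
  k <- min(length(keep), maxVectors)
  U <- sv$u[, seq_len(k), drop = FALSE]
  variates <- crossprod(U, xc)
  bins <- lapply(seq_len(k), function(i) {
    vmax <- max(abs(variates[i, ]))
    seq(-vmax, vmax, length.out = nLevels)
  })
  new("GroupCodec", basis = U, singularValues = sv$d[seq_len(k)],
      nLevels = as.integer(nLevels), binCenters = bins, mean = mu)
}

quantizeVariate <- function(v, centers) {
  width <- centers[2L] - centers[1L]
  idx <- as.integer(round((v - centers[1L]) / width)) + 1L
  pmin(pmax(idx, 1L), length(centers))
}

#' Encode frames to a discrete observation
#'
#' @param frames array (H x W x C x T or H x W x T).
#' @param partition a BlockPartition.
#' @param codecs list of GroupCodec, one per group.
#' @param breaks episode-start voxel-time indices (default one episode).
#' @return a \linkS4class{DiscreteObservation}.
#' @export
encodeFrames <- function(frames, partition, codecs, breaks = 1L) {
  frames <- asFrameArray(frames)
  d <- dim(frames)
  if (!identical(d[1:3], partition@imageShape))
    stop("frame shape does not match the partition")
  if (d[4L] %% partition@R != 0L) stop("frame count must be divisible by R")
  ng <- nGroups(partition)
  Tn <- d[4L] %/% partition@R
  idx <- vector("list", ng)
  alphabet <- vector("list", ng)
  for (g in seq_len(ng)) {
    cd <- codecs[[g]]
    k <- ncol(cd@basis)
    if (k == 0L) {
      idx[[g]] <- matrix(1L, 1L, Tn)
      alphabet[[g]] <- 1L
      next
    }
    x <- blockMatrix(frames, partition, g)
    v <- crossprod(cd@basis, x - cd@mean)
    m <- matrix(0L, k, Tn)
    for (i in seq_len(k)) m[i, ] <- quantizeVariate(v[i, ], cd@binCenters[[i]])
    idx[[g]] <- m
    alphabet[[g]] <- rep(cd@nLevels, k)
  }
  new("DiscreteObservation", idx = idx, alphabet = alphabet,
      R = partition@R, breaks = as.integer(breaks))
}

#' Decode a discrete observation back to frames
#'
#' Inverts \code{\link{encodeFrames}} up to the per-variate half-bin
#' quantization error: each block is the codec mean plus the basis applied to
#' the bin centres of the stored indices.
#'
#' @param obs a DiscreteObservation produced by \code{encodeFrames}.
#' @param partition the BlockPartition used to encode.
#' @param codecs the codecs used to encode.
#' @return frame array (H x W x C x T).
#' @export
decodeFrames <- function(obs, partition, codecs) {
  ng <- nGroups(partition)
  Tn <- ncol(obs@idx[[1L]])
  d <- partition@imageShape
  R <- partition@R
  frames <- array(0, c(d, Tn * R))
  for (g in seq_len(ng)) {
    cd <- codecs[[g]]
    px <- groupPixels(partition, g)
    k <- ncol(cd@basis)
    for (t in seq_len(Tn)) {
      if (k > 0L) {
        v <- vapply(seq_len(k), function(i) cd@binCenters[[i]][obs@idx[[g]][i, t]],
                    numeric(1L))
        vec <- cd@mean + as.vector(cd@basis %*% v)
      } else vec <- cd@mean
      blk <- array(vec, c(partition@blockShape, d[3L], R))
      frames[px$rows, px$cols, , ((t - 1L) * R + 1L):(t * R)] <- blk
    }
  }
  frames
}

# Worst-case absolute pixel reconstruction error for encode->decode of a
# training frame: half the widest bin per component, through the basis.
codecErrorBound <- function(codec) {
  k <- ncol(codec@basis)
  if (k == 0L) return(0)
  half <- vapply(codec@binCenters, function(b) (b[2L] - b[1L]) / 2, numeric(1L))
  sum(apply(abs(codec@basis), 2L, max) * half)
}
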