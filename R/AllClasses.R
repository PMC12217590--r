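#' @import methods
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head tail
NULL

#' Block partition of an image stack
#'
#' Describes the deterministic row-major tessellation of frames into
#' non-overlapping pixel blocks (spin blocks), together with the temporal
#' grouping factor \code{R}: how many consecutive frames are concatenated into
#' one time-colour-pixel voxel.
#'
#' @slot imageShape integer(3): height, width, channels in pixels.
#' @slot blockShape integer(2): block height and width in pixels.
#' @slot R integer(1): frames per voxel.
#' @slot centroids numeric matrix (nGroups x 2): block centres (row, col).
#' @export
setClass("BlockPartition",
  representation(imageShape = "integer", blockShape = "integer",
                 R = "integer", centroids = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@imageShape) != 3L) msg <- c(msg, "imageShape must be length 3")
    if (length(object@blockShape) != 2L) msg <- c(msg, "blockShape must be length 2")
    if (object@R < 1L) msg <- c(msg, "R must be >= 1")
    if (length(msg) == 0L &&
        (object@imageShape[1L] %% object@blockShape[1L] != 0L ||
         object@imageShape[2L] %% object@blockShape[2L] != 0L))
      msg <- c(msg, "blocks must tile the image exactly")
    if (length(msg)) msg else TRUE
  })

#' Per-group SVD codec
#'
#' Orthonormal basis of left singular vectors for one pixel block, the
#' associated singular values, and the uniform, zero-centred quantization
#' grid used to map continuous singular variates to discrete levels.
#'
#' @slot basis matrix (blockDim x k) of retained left singular vectors.
#' @slot singularValues numeric(k), non-increasing.
#' @slot nLevels odd integer: quantization levels per variate.
#' @slot binCenters list of numeric vectors (length nLevels), one per variate,
#'   symmetric about zero.
#' @slot mean numeric(blockDim): per-group training mean.
#' @export
setClass("GroupCodec",
  representation(basis = "matrix", singularValues = "numeric",
                 nLevels = "integer", binCenters = "list", mean = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@basis)
    if (object@nLevels %% 2L == 0L) msg <- c(msg, "nLevels must be odd")
    if (k > 0L) {
      gram <- crossprod(object@basis)
      if (max(abs(gram - diag(k))) > 1e-8)
        msg <- c(msg, "basis columns must be orthonormal (1e-8)")
      if (any(diff(object@singularValues) > 1e-12))
        msg <- c(msg, "singular values must be non-increasing")
    }
    for (b in object@binCenters)
      if (max(abs(b + rev(b))) > 1e-9)
        msg <- c(msg, "bin centers must be symmetric about zero")
    if (length(msg)) msg else TRUE
  })

#' Discrete first-level observation
#'
#' Per-group, per-variate categorical index sequences (time in columns), the
#' alphabet sizes, the frontend temporal factor and the episode break points.
#' Index \code{t} counts voxel steps (\code{R} frames each). \code{breaks}
#' lists the voxel-time indices that start a new episode; transitions are
#' never recorded, and never inferred, across a break.
#'
#' @slot idx list over groups of integer matrices (nVariates x T).
#' @slot alphabet list over groups of integer vectors (per-variate sizes).
#' @slot R integer: frames per voxel step (1 for direct symbolic observations).
#' @slot breaks integer vector of episode-start time indices (always contains 1).
#' @export
setClass("DiscreteObservation",
  representation(idx = "list", alphabet = "list", R = "integer",
                 breaks = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@idx) != length(object@alphabet))
      msg <- c(msg, "idx and alphabet must have one entry per group")
    for (g in seq_along(object@idx)) {
      m <- object@idx[[g]]
      a <- object@alphabet[[g]]
      if (nrow(m) != length(a)) { msg <- c(msg, "variate count mismatch"); break }
      if (nrow(m) > 0L && (min(m) < 1L || any(m > a)))
        { msg <- c(msg, "symbol index outside alphabet"); break }
    }
    if (length(object@breaks) == 0L || object@breaks[1L] != 1L)
      msg <- c(msg, "breaks must start with 1")
    if (length(msg)) msg else TRUE
  })

#' One hierarchical level of a renormalizing generative model
#'
#' A level holds, for each of its groups (latent factors), the likelihood
#' mappings to the groups below, the within-segment transition tensor, and the
#' grouping metadata. The mapping for child (or modality) \code{c} of group
#' \code{g} is a list with a \code{D} matrix (child initial states x own
#' states) and, above level 1, an \code{E} matrix (child paths x own states).
#' Children of distinct groups never overlap (the partition property), which
#' keeps all mappings small matrices.
#'
#' @slot A list over groups; each a list over children of list(D=, E=).
#' @slot B list over groups of 3-d arrays (state x state x path).
#' @slot children list over groups of integer vectors: indices of the child
#'   groups at the level below (for level 1: variate indices within the group).
#' @slot R integer: number of time steps at the level below spanned by one
#'   step at this level (1 at level 1).
#' @slot nStates,nPaths integer vectors per group.
#' @export
setClass("ModelLevel",
  representation(A = "list", B = "list", children = "list", R = "integer",
                 nStates = "integer", nPaths = "integer"),
  validity = function(object) {
    ng <- length(object@A)
    if (length(object@B) != ng || length(object@children) != ng ||
        length(object@nStates) != ng || length(object@nPaths) != ng)
      return("per-group slots must have equal length")
    for (g in seq_len(ng)) {
      if (any(object@A[[g]][[1L]]$D < 0)) return("negative counts in A")
      if (any(object@B[[g]] < 0)) return("negative counts in B")
    }
    TRUE
  })

#' Renormalizing generative model
#'
#' An ordered stack of \linkS4class{ModelLevel}s (level 1 adjacent to the
#' observations), the image frontend (partition + codecs) when the model was
#' learned from encoded frames, priors over the top-level initial state and
#' paths, optional outcome preferences, and the global Dirichlet count floor
#' applied wherever expected logarithms of count tensors are taken.
#'
#' @slot levels list of ModelLevel, bottom first.
#' @slot partition BlockPartition or NULL (stored in a list slot).
#' @slot codecs list of GroupCodec (empty for symbolic observations).
#' @slot labelLevel logical: is the top level a supervision (label) level?
#' @slot Dtop numeric counts over top states; Etop over top path slices.
#' @slot Cpref list of preference count vectors (may be empty).
#' @slot floor numeric count floor (default 1/32).
#' @slot version character format version.
#' @export
setClass("RGModel",
  representation(levels = "list", partition = "list", codecs = "list",
                 labelLevel = "logical", Dtop = "numeric", Etop = "numeric",
                 Cpref = "list", floor = "numeric", version = "character"),
  validity = function(object) {
    msg <- character()
    nl <- length(object@levels)
    if (nl == 0L) return("model must have at least one level")
    for (n in seq_len(nl)) {
      lev <- object@levels[[n]]
      if (!is(lev, "ModelLevel")) return("levels must be ModelLevel objects")
      if (n > 1L) {
        below <- object@levels[[n - 1L]]
        kids <- sort(unlist(lev@children))
        if (!identical(kids, seq_along(below@A)))
          msg <- c(msg, sprintf("level %d children must partition level %d groups", n, n - 1L))
        for (g in seq_along(lev@A))
          for (ci in seq_along(lev@children[[g]])) {
            ch <- lev@children[[g]][ci]
            if (nrow(lev@A[[g]][[ci]]$D) != below@nStates[ch])
              msg <- c(msg, "D map rows must equal child state count")
            E <- lev@A[[g]][[ci]]$E
            if (!is.null(E) && nrow(E) != below@nPaths[ch])
              msg <- c(msg, "E map rows must equal child path count")
          }
      }
    }
    top <- object@levels[[nl]]
    if (length(top@A) != 1L) msg <- c(msg, "top level must have a single group")
    if (length(object@Dtop) != top@nStates[1L]) msg <- c(msg, "Dtop length mismatch")
    if (object@floor < 0) msg <- c(msg, "floor must be >= 0")
    if (length(msg)) unique(msg) else TRUE
  })

#' Posterior beliefs after model inversion
#'
#' Per-level, per-group categorical expectations over states (per time step at
#' that level) and paths (per segment), the accumulated variational free
#' energy per level (nats), and the total log evidence \code{logZ}
#' (\code{-logZ} is the total free energy; \code{logZ} the ELBO).
#'
#' @slot s list over levels of lists over groups of matrices (nStates x T).
#' @slot u list over levels of lists over groups of matrices (nPaths x T-ish).
#' @slot F numeric per-level free energies (nats).
#' @slot logZ numeric(1) total log evidence.
#' @slot topSeq integer vector: maximum a posteriori top-state trajectory.
#' @export
setClass("Posterior",
  representation(s = "list", u = "list", F = "numeric", logZ = "numeric",
                 topSeq = "integer"))

#' Episode log from a grid-world environment
#'
#' Frames are stored as discrete cell-state matrices; \code{states} keeps the
#' full engine state (including ball velocity) at every step so that play can
#' be resumed from any recorded time point. \code{segments} holds the
#' reward-bracketed index ranges selected for structure learning.
#'
#' @slot frames list of integer matrices (H x W cell states).
#' @slot states list of engine states.
#' @slot actions integer vector; rewards, misses logical vectors.
#' @slot segments data.frame with columns from, to, chain (chain id marks
#'   contiguous runs; consecutive segments in one chain are contiguous in time).
#' @export
setClass("EpisodeLog",
  representation(frames = "list", states = "list", actions = "integer",
                 rewards = "logical", misses = "logical",
                 segments = "data.frame"))

setMethod("show", "BlockPartition", function(object) {
  g <- prod(object@imageShape[1:2] %/% object@blockShape)
  cat(sprintf("BlockPartition: %dx%dx%d image, %dx%d blocks (%d groups), R=%d\n",
              object@imageShape[1], object@imageShape[2], object@imageShape[3],
              object@blockShape[1], object@blockShape[2], g, object@R))
})

setMethod("show", "GroupCodec", function(object) {
  cat(sprintf("GroupCodec: %d retained components, %d quantization levels\n",
              ncol(object@basis), object@nLevels))
})

setMethod("show", "DiscreteObservation", function(object) {
  Tn <- if (length(object@idx)) ncol(object@idx[[1L]]) else 0L
  cat(sprintf("DiscreteObservation: %d groups, %d voxel steps (R=%d), %d episode(s)\n",
              length(object@idx), Tn, object@R, length(object@breaks)))
})

setMethod("show", "ModelLevel", function(object) {
  cat(sprintf("ModelLevel: %d group(s); states %s; paths %s; R=%d\n",
              length(object@A), paste(object@nStates, collapse = ","),
              paste(object@nPaths, collapse = ","), object@R))
})

setMethod("show", "RGModel", function(object) {
  cat(sprintf("RGModel with %d level(s)%s, floor=%g\n", length(object@levels),
              if (object@labelLevel) " (top = label level)" else "", object@floor))
  for (n in seq_along(object@levels)) {
    lev <- object@levels[[n]]
    cat(sprintf("  level %d: %d group(s), %d state(s), R=%d\n", n,
                length(lev@A), sum(lev@nStates), lev@R))
  }
})

setMethod("show", "Posterior", function(object) {
  cat(sprintf("Posterior: %d level(s), ELBO = %.4f nats\n",
              length(object@s), object@logZ))
})

setMethod("show", "EpisodeLog", function(object) {
  cat(sprintf("EpisodeLog: %d frames, %d hits, %d misses, %d selected segment(s)\n",
              length(object@frames), sum(object@rewards), sum(object@misses),
              nrow(object@segments)))
})
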