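#' Number of hierarchical levels
#' @param x an RGModel
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname nLevels
setMethod("nLevels", "RGModel", function(x) length(x@levels))

#' State counts per level
#'
#' Total number of latent states at each level (summed over that level's
#' groups).
#' @param x an RGModel
#' @export
setGeneric("levelStates", function(x) standardGeneric("levelStates"))

#' @rdname levelStates
setMethod("levelStates", "RGModel", function(x)
  vapply(x@levels, function(l) sum(l@nStates), integer(1L)))

#' Temporal span of one top-level state
#'
#' Number of first-level time steps generated by a single top-level state:
#' the product of the temporal grouping factors over levels. Does not include
#' the frontend factor (frames per voxel).
#' @param x an RGModel
#' @export
setGeneric("temporalSpan", function(x) standardGeneric("temporalSpan"))

#' @rdname temporalSpan
setMethod("temporalSpan", "RGModel", function(x)
  prod(vapply(x@levels, function(l) l@R, integer(1L))))

#' Frontend codecs of a model
#' @param x an RGModel
#' @export
setGeneric("codecs", function(x) standardGeneric("codecs"))

#' @rdname codecs
setMethod("codecs", "RGModel", function(x) x@codecs)

#' Count floor of a model
#' @param x an RGModel
#' @export
setGeneric("countFloor", function(x) standardGeneric("countFloor"))

#' @rdname countFloor
setMethod("countFloor", "RGModel", function(x) x@floor)

#' Replace the count floor
#' @param x an RGModel
#' @param value new non-negative floor
#' @export
setGeneric("countFloor<-", function(x, value) standardGeneric("countFloor<-"))

#' @rdname countFloor
setMethod("countFloor<-", "RGModel", function(x, value) {
  stopifnot(value >= 0)
  x@floor <- value
  x
})

#' Free energy per level
#' @param x a Posterior
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname freeEnergy
setMethod("freeEnergy", "Posterior", function(x) x@F)

#' Evidence lower bound
#' @param x a Posterior
#' @export
setGeneric("elbo", function(x) standardGeneric("elbo"))

#' @rdname elbo
setMethod("elbo", "Posterior", function(x) x@logZ)

#' Maximum a posteriori top-state trajectory
#' @param x a Posterior
#' @export
setGeneric("topStates", function(x) standardGeneric("topStates"))

#' @rdname topStates
setMethod("topStates", "Posterior", function(x) x@topSeq)
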