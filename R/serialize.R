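# Model container: a directory with a human-readable manifest.json describing
# shapes, grouping and codec metadata, and arrays.rds holding every count
# tensor and codec matrix at full precision.

RGM_FORMAT_VERSION <- "rgm-container-1"

#' Save a renormalizing generative model
#'
#' Writes \code{path/manifest.json} (structure metadata and format version)
#' and \code{path/arrays.rds} (all numeric payloads). The round trip through
#' \code{\link{loadModel}} is bit-exact.
#'
#' @param m an \linkS4class{RGModel}.
#' @param path directory to create or overwrite.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(m, path) {
  stopifnot(is(m, "RGModel"))
  validObject(m)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = RGM_FORMAT_VERSION,
    nLevels = length(m@levels),
    labelLevel = m@labelLevel,
    floor = m@floor,
    levels = lapply(m@levels, function(l) list(
      nGroups = length(l@A), R = l@R,
      nStates = as.integer(l@nStates), nPaths = as.integer(l@nPaths),
      children = lapply(l@children, as.integer))),
    nCodecs = length(m@codecs),
    partition = if (length(m@partition)) list(
      imageShape = as.integer(m@partition[[1L]]@imageShape),
      blockShape = as.integer(m@partition[[1L]]@blockShape),
      R = m@partition[[1L]]@R) else NULL)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  arrays <- list(
    levels = lapply(m@levels, function(l) list(A = l@A, B = l@B)),
    Dtop = m@Dtop, Etop = m@Etop, Cpref = m@Cpref,
    codecs = lapply(m@codecs, function(cd) list(
      basis = cd@basis, singularValues = cd@singularValues,
      nLevels = cd@nLevels, binCenters = cd@binCenters, mean = cd@mean)),
    centroids = if (length(m@partition)) m@partition[[1L]]@centroids else NULL)
  saveRDS(arrays, file.path(path, "arrays.rds"))
  invisible(path)
}

#' Load a renormalizing generative model
#'
#' @param path directory written by \code{\link{saveModel}}.
#' @return an \linkS4class{RGModel}.
#' @export
loadModel <- function(path) {
  mf <- file.path(path, "manifest.json")
  af <- file.path(path, "arrays.rds")
  if (!file.exists(mf)) stop("model container is missing manifest.json")
  if (!file.exists(af)) stop("model container is missing arrays.rds")
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = FALSE),
                       error = function(e) stop("corrupt manifest: ", conditionMessage(e)))
  if (!identical(manifest$format, RGM_FORMAT_VERSION))
    stop("unsupported container format version: ", manifest$format)
  arrays <- tryCatch(readRDS(af),
                     error = function(e) stop("corrupt array container: ", conditionMessage(e)))
  if (length(arrays$levels) != manifest$nLevels)
    stop("truncated container: level count mismatch")
  levels <- vector("list", manifest$nLevels)
  for (n in seq_len(manifest$nLevels)) {
    meta <- manifest$levels[[n]]
    levels[[n]] <- new("ModelLevel",
      A = arrays$levels[[n]]$A, B = arrays$levels[[n]]$B,
      children = lapply(meta$children, function(v) as.integer(unlist(v))),
      R = as.integer(meta$R),
      nStates = as.integer(unlist(meta$nStates)),
      nPaths = as.integer(unlist(meta$nPaths)))
  }
  codecs <- lapply(arrays$codecs, function(cd)
    new("GroupCodec", basis = cd$basis, singularValues = cd$singularValues,
        nLevels = cd$nLevels, binCenters = cd$binCenters, mean = cd$mean))
  partition <- list()
  if (!is.null(manifest$partition)) {
    p <- manifest$partition
    partition <- list(new("BlockPartition",
      imageShape = as.integer(unlist(p$imageShape)),
      blockShape = as.integer(unlist(p$blockShape)),
      R = as.integer(p$R), centroids = arrays$centroids))
  }
  m <- new("RGModel", levels = levels, partition = partition, codecs = codecs,
           labelLevel = isTRUE(manifest$labelLevel),
           Dtop = arrays$Dtop, Etop = arrays$Etop,
           Cpref = if (is.null(arrays$Cpref)) list() else arrays$Cpref,
           floor = manifest$floor, version = RGM_FORMAT_VERSION)
  validObject(m)
  m
}
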