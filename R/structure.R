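# Fast structure learning: self-assembly of a renormalizing generative model
# from a discrete observation sequence by recording unique states and unique
# transitions, then coarse-graining over space (merging neighbouring groups)
# and time (segments of R steps) until a single top-level factor remains.
# The procedure is deterministic and lossless: generating from the inferred
# top trajectory reproduces the training sequence exactly.

columnKeys <- function(m) {
  if (nrow(m) == 1L) as.character(m[1L, ])
  else apply(m, 2L, paste, collapse = ",")
}

#' Unique state columns of a discrete sequence
#'
#' Scans a per-group observation matrix (variates x time) and records one
#' latent state per unique symbol combination, in order of first appearance.
#' The returned likelihood matrices are one-hot by column.
#'
#' @param m integer matrix (nVariates x T) of symbol indices.
#' @param alphabet integer vector of per-variate alphabet sizes.
#' @return list with \code{states} (variates x nStates matrix of unique
#'   columns), \code{seq} (time to state-index mapping), and \code{A} (list
#'   per variate of one-hot likelihood matrices, alphabet x nStates).
#' @export
uniqueStateColumns <- function(m, alphabet = apply(m, 1L, max)) {
  if (ncol(m) == 0L) stop("empty sequence")
  keys <- columnKeys(m)
  first <- !duplicated(keys)
  states <- m[, first, drop = FALSE]
  sq <- match(keys, keys[first])
  A <- lapply(seq_len(nrow(m)), function(v) {
    a <- matrix(0, alphabet[v], ncol(states))
    a[cbind(states[v, ], seq_len(ncol(states)))] <- 1
    a
  })
  list(states = states, seq = sq, A = A)
}

#' Unique transitions of a state-index sequence
#'
#' Records each observed successor relation in a transition tensor
#' (state x state x path). When a source state has several distinct observed
#' successors, each successor occupies its own path slice; slices are indexed
#' by order of first appearance. Transitions across episode breaks are not
#' recorded.
#'
#' @param s integer state-index sequence (length >= 2).
#' @param nStates number of states (defaults to \code{max(s)}).
#' @param breaks episode-start indices.
#' @return list with \code{B} (nStates x nStates x nPaths array, one-hot by
#'   column for observed sources), \code{u} (path index per transition; NA at
#'   breaks), \code{nPaths}.
#' @export
uniqueTransitions <- function(s, nStates = max(s), breaks = 1L) {
  succ <- list()  # per path slice: successor of each source (NA = unset)
  u <- rep(NA_integer_, max(length(s) - 1L, 0L))
  for (t in seq_len(length(s) - 1L)) {
    if ((t + 1L) %in% breaks) next
    a <- s[t]; b <- s[t + 1L]
    p <- 0L
    for (j in seq_along(succ)) {
      if (!is.na(succ[[j]][a]) && succ[[j]][a] == b) { p <- j; break }
    }
    if (p == 0L) for (j in seq_along(succ)) {
      if (is.na(succ[[j]][a])) { succ[[j]][a] <- b; p <- j; break }
    }
    if (p == 0L) {
      succ[[length(succ) + 1L]] <- rep(NA_integer_, nStates)
      succ[[length(succ)]][a] <- b
      p <- length(succ)
    }
    u[t] <- p
  }
  nP <- max(length(succ), 1L)
  B <- array(0, c(nStates, nStates, nP))
  for (j in seq_along(succ)) {
    set <- which(!is.na(succ[[j]]))
    B[cbind(succ[[j]][set], set, j)] <- 1
  }
  list(B = B, u = u, nPaths = nP)
}

# Segment-constrained transition recording: one path slice must explain all
# R-1 transitions inside each segment. For R = 2 this coincides with
# uniqueTransitions. Breaks must be aligned to segment starts.
assignSegmentPaths <- function(s, R, nStates, breaks) {
  Tn <- length(s)
  nSeg <- Tn %/% R
  if (R < 2L) {
    return(list(B = array(0, c(nStates, nStates, 1L)),
                u = rep(1L, nSeg), nPaths = 1L))
  }
  succ <- list()
  u <- integer(nSeg)
  for (sg in seq_len(nSeg)) {
    t0 <- (sg - 1L) * R + 1L
    ab <- cbind(s[t0:(t0 + R - 2L)], s[(t0 + 1L):(t0 + R - 1L)])
    p <- 0L
    for (j in seq_along(succ)) {
      v <- succ[[j]]
      ok <- TRUE
      for (r in seq_len(nrow(ab))) {
        x <- v[ab[r, 1L]]
        if (!is.na(x) && x != ab[r, 2L]) { ok <- FALSE; break }
        v[ab[r, 1L]] <- ab[r, 2L]  # tentative fill (also guards within-segment clashes)
      }
      if (ok) { succ[[j]] <- v; p <- j; break }
    }
    if (p == 0L) {
      v <- rep(NA_integer_, nStates)
      ok <- TRUE
      for (r in seq_len(nrow(ab))) {
        x <- v[ab[r, 1L]]
        if (!is.na(x) && x != ab[r, 2L]) { ok <- FALSE; break }
        v[ab[r, 1L]] <- ab[r, 2L]
      }
      if (!ok) stop("segment revisits a source state with conflicting successors; reduce R")
      succ[[length(succ) + 1L]] <- v
      p <- length(succ)
    }
    u[sg] <- p
  }
  nP <- max(length(succ), 1L)
  B <- array(0, c(nStates, nStates, nP))
  for (j in seq_along(succ)) {
    set <- which(!is.na(succ[[j]]))
    B[cbind(succ[[j]][set], set, j)] <- 1
  }
  list(B = B, u = u, nPaths = nP)
}

#' Coarse-grain state and path sequences into parent super-symbols
#'
#' Partitions each group's sequence into segments of \code{R} steps, pairs
#' the segment-initial state with the segment's path, and joins the children
#' named by \code{merge} into parent groups whose states are the unique
#' (initial state, path) tuples, in order of first appearance.
#'
#' @param stateSeqs list per child group of state-index sequences.
#' @param pathSeqs list per child group of per-segment path indices.
#' @param R temporal grouping factor.
#' @param merge list: one integer vector of child indices per parent group.
#' @return list with \code{seq} (per parent group), \code{maps} (per parent
#'   group: per child list(D=, E=) one-hot matrices), \code{nStates}.
#' @export
coarseGrain <- function(stateSeqs, pathSeqs, R, merge) {
  Tn <- length(stateSeqs[[1L]])
  nSeg <- Tn %/% R
  t0 <- (seq_len(nSeg) - 1L) * R + 1L
  out <- list(seq = vector("list", length(merge)),
              maps = vector("list", length(merge)),
              nStates = integer(length(merge)))
  for (G in seq_along(merge)) {
    ch <- merge[[G]]
    tup <- matrix(0L, 2L * length(ch), nSeg)
    for (i in seq_along(ch)) {
      tup[2L * i - 1L, ] <- stateSeqs[[ch[i]]][t0]
      tup[2L * i, ] <- pathSeqs[[ch[i]]][seq_len(nSeg)]
    }
    keys <- columnKeys(tup)
    first <- !duplicated(keys)
    uniq <- tup[, first, drop = FALSE]
    K <- ncol(uniq)
    out$seq[[G]] <- match(keys, keys[first])
    out$nStates[G] <- K
    out$maps[[G]] <- lapply(seq_along(ch), function(i) {
      nSt <- max(stateSeqs[[ch[i]]])
      nPa <- max(pathSeqs[[ch[i]]])
      D <- matrix(0, nSt, K); E <- matrix(0, nPa, K)
      D[cbind(uniq[2L * i - 1L, ], seq_len(K))] <- 1
      E[cbind(uniq[2L * i, ], seq_len(K))] <- 1
      list(D = D, E = E)
    })
  }
  out
}

checkBreaks <- function(breaks, R, nSeg) {
  if (any((breaks - 1L) %% R != 0L))
    stop("episode breaks must be aligned to segment boundaries")
  nb <- (breaks - 1L) %/% R + 1L
  sort(unique(nb[nb <= nSeg]))
}

#' Fast structure learning
#'
#' Self-assembles a renormalizing generative model from a discrete
#' observation sequence. Level 1 records unique symbol combinations per
#' group; each ascent of the schedule records unique within-segment
#' transitions (path slices), coarse-grains time by \code{R} and merges
#' groups, until a single top-level factor remains. Top-level transitions are
#' recorded per step with one path slice per distinct successor. The top
#' initial-state and path priors are uniform counts.
#'
#' @param obs a \linkS4class{DiscreteObservation}.
#' @param schedule list of ascents; each a list with \code{R} (integer) and
#'   \code{merge} (list of child-index vectors, one per parent group).
#' @param floor Dirichlet count floor stored on the model (default 1/32).
#' @param partition,codecs optional frontend to attach for decoding.
#' @return an \linkS4class{RGModel}.
#' @export
fastStructureLearn <- function(obs, schedule, floor = 1 / 32,
                               partition = NULL, codecs = list()) {
  ng <- length(obs@idx)
  Tn <- ncol(obs@idx[[1L]])
  if (Tn == 0L) stop("empty observation sequence")
  # level 1: unique symbol combinations per group
  usc <- lapply(seq_len(ng), function(g)
    uniqueStateColumns(obs@idx[[g]], obs@alphabet[[g]]))
  levels <- list(new("ModelLevel",
    A = lapply(usc, function(u) lapply(u$A, function(D) list(D = D, E = NULL))),
    B = lapply(usc, function(u) array(0, c(ncol(u$states), ncol(u$states), 1L))),
    children = lapply(seq_len(ng), function(g) seq_along(obs@alphabet[[g]])),
    R = 1L,
    nStates = vapply(usc, function(u) ncol(u$states), integer(1L)),
    nPaths = rep(1L, ng)))
  stateSeqs <- lapply(usc, `[[`, "seq")
  breaks <- obs@breaks

  for (asc in schedule) {
    R <- as.integer(asc$R)
    merge <- asc$merge
    if (!identical(as.integer(sort(unlist(merge))), seq_len(ng)))
      stop("merge must partition the current groups")
    nSeg <- Tn %/% R
    if (nSeg * R != Tn) {
      warning(sprintf("dropping trailing %d step(s) not filling a segment", Tn - nSeg * R))
      stateSeqs <- lapply(stateSeqs, function(s) s[seq_len(nSeg * R)])
      Tn <- nSeg * R
    }
    n <- length(levels)
    nStates <- levels[[n]]@nStates
    tr <- lapply(seq_len(ng), function(g)
      assignSegmentPaths(stateSeqs[[g]], R, nStates[g], breaks))
    lev <- levels[[n]]
    lev@B <- lapply(tr, `[[`, "B")
    lev@nPaths <- vapply(tr, `[[`, integer(1L), "nPaths")
    levels[[n]] <- lev
    cg <- coarseGrain(stateSeqs, lapply(tr, `[[`, "u"), R, merge)
    # pad maps to the recorded state/path counts (coarseGrain sizes by max index)
    maps <- lapply(seq_along(merge), function(G)
      lapply(seq_along(merge[[G]]), function(i) {
        ch <- merge[[G]][i]
        m <- cg$maps[[G]][[i]]
        D <- matrix(0, nStates[ch], ncol(m$D)); D[seq_len(nrow(m$D)), ] <- m$D
        E <- matrix(0, lev@nPaths[ch], ncol(m$E)); E[seq_len(nrow(m$E)), ] <- m$E
        list(D = D, E = E)
      }))
    levels[[length(levels) + 1L]] <- new("ModelLevel",
      A = maps,
      B = lapply(cg$nStates, function(K) array(0, c(K, K, 1L))),
      children = merge, R = R,
      nStates = cg$nStates, nPaths = rep(1L, length(merge)))
    stateSeqs <- cg$seq
    ng <- length(merge)
    Tn <- nSeg
    breaks <- checkBreaks(breaks, R, nSeg)
  }
  if (ng != 1L)
    stop("schedule must terminate in a single top-level group")
  # top-level dynamics: per-step unique transitions within episodes
  nTop <- length(levels)
  topStates <- levels[[nTop]]@nStates[1L]
  tr <- uniqueTransitions(stateSeqs[[1L]], topStates, breaks)
  lev <- levels[[nTop]]
  lev@B <- list(tr$B)
  lev@nPaths <- tr$nPaths
  levels[[nTop]] <- lev
  m <- new("RGModel", levels = levels,
           partition = if (is.null(partition)) list() else list(partition),
           codecs = codecs, labelLevel = FALSE,
           Dtop = rep(1, topStates), Etop = rep(1, tr$nPaths),
           Cpref = list(), floor = floor, version = RGM_FORMAT_VERSION)
  validObject(m)
  m
}

# Reconstruct, per level, the (child state, child path) tuple behind each
# parent state, as a key string -> parent state lookup.
levelKeyMap <- function(lev) {
  K <- lev@nStates[1L]  # caller indexes per group
  lapply(seq_along(lev@A), function(G) {
    K <- lev@nStates[G]
    tup <- matrix(0L, 2L * length(lev@children[[G]]), K)
    for (i in seq_along(lev@children[[G]])) {
      tup[2L * i - 1L, ] <- apply(lev@A[[G]][[i]]$D, 2L, which.max)
      tup[2L * i, ] <- apply(lev@A[[G]][[i]]$E, 2L, which.max)
    }
    keys <- columnKeys(tup)
    stats::setNames(seq_len(K), keys)
  })
}

#' Deterministically compress an observation through a learned model
#'
#' The lossless recognition path: matches observed symbol combinations to the
#' model's likelihood columns, observed transitions to path slices, and
#' coarse-grained tuples to parent states, exactly as during structure
#' learning. Errors if the observation contains a combination or transition
#' the model has never seen.
#'
#' @param m an RGModel (without label level).
#' @param obs a DiscreteObservation compatible with the model's first level.
#' @return list with \code{top} (top state sequence), \code{states} and
#'   \code{paths} (per level, per group sequences).
#' @export
compressSequence <- function(m, obs) {
  levels <- m@levels
  nl <- length(levels) - if (m@labelLevel) 1L else 0L
  ng <- length(levels[[1L]]@A)
  breaks <- obs@breaks
  # level 1 matching
  stateSeqs <- vector("list", ng)
  for (g in seq_len(ng)) {
    states <- do.call(rbind, lapply(levels[[1L]]@A[[g]], function(mod)
      apply(mod$D, 2L, which.max)))
    keys <- columnKeys(states)
    sq <- match(columnKeys(obs@idx[[g]]), keys)
    if (anyNA(sq)) stop("observation contains symbol combinations unknown to the model")
    stateSeqs[[g]] <- sq
  }
  allStates <- list(stateSeqs)
  allPaths <- list()
  for (n in seq_len(nl - 1L)) {
    lev <- levels[[n]]
    up <- levels[[n + 1L]]
    R <- up@R
    Tn <- length(stateSeqs[[1L]])
    nSeg <- Tn %/% R
    pathSeqs <- vector("list", length(stateSeqs))
    for (g in seq_along(stateSeqs)) {
      B <- lev@B[[g]]
      s <- stateSeqs[[g]]
      u <- integer(nSeg)
      for (sg in seq_len(nSeg)) {
        t0 <- (sg - 1L) * R + 1L
        if (R < 2L) { u[sg] <- 1L; next }
        found <- 0L
        for (p in seq_len(dim(B)[3L])) {
          ok <- TRUE
          for (tau in seq_len(R - 1L)) {
            if (B[s[t0 + tau], s[t0 + tau - 1L], p] == 0) { ok <- FALSE; break }
          }
          if (ok) { found <- p; break }
        }
        if (found == 0L) stop("observation contains a transition unknown to the model")
        u[sg] <- found
      }
      pathSeqs[[g]] <- u
    }
    km <- levelKeyMap(up)
    newSeqs <- vector("list", length(up@A))
    for (G in seq_along(up@A)) {
      ch <- up@children[[G]]
      tup <- matrix(0L, 2L * length(ch), nSeg)
      for (i in seq_along(ch)) {
        tup[2L * i - 1L, ] <- stateSeqs[[ch[i]]][(seq_len(nSeg) - 1L) * R + 1L]
        tup[2L * i, ] <- pathSeqs[[ch[i]]]
      }
      sq <- unname(km[[G]][columnKeys(tup)])
      if (anyNA(sq)) stop("observation contains a super-symbol unknown to the model")
      newSeqs[[G]] <- sq
    }
    allPaths[[n]] <- pathSeqs
    stateSeqs <- newSeqs
    breaks <- (breaks - 1L) %/% R + 1L
    allStates[[n + 1L]] <- stateSeqs
  }
  list(top = stateSeqs[[1L]], states = allStates, paths = allPaths)
}

#' Add a supervision (label) level
#'
#' Equips a model with a new top level whose states are class labels; the
#' likelihood column for class k spreads (unit counts) over the exemplar-level
#' states observed with label k. Exemplars are the episodes of \code{obs};
#' each episode must span a whole number of top-level steps, and its initial
#' top state is taken as the exemplar state.
#'
#' @param m an RGModel without a label level.
#' @param labels factor or integer vector, one label per episode.
#' @param obs the training DiscreteObservation (used to locate exemplar
#'   states), or \code{exemplarStates} directly.
#' @param exemplarStates optional integer vector of top states per exemplar.
#' @return an RGModel with \code{labelLevel = TRUE}.
#' @export
addLabelLevel <- function(m, labels, obs = NULL, exemplarStates = NULL) {
  if (m@labelLevel) stop("model already has a label level")
  if (is.null(exemplarStates)) {
    if (is.null(obs)) stop("provide obs or exemplarStates")
    cs <- compressSequence(m, obs)
    span <- temporalSpan(m)
    starts <- (obs@breaks - 1L) %/% span + 1L
    exemplarStates <- cs$top[starts]
  }
  labels <- as.integer(factor(labels))
  if (length(labels) != length(exemplarStates))
    stop("label count must match exemplar count")
  K <- max(labels)
  nEx <- m@levels[[length(m@levels)]]@nStates[1L]
  D <- matrix(0, nEx, K)
  for (i in seq_along(labels)) D[exemplarStates[i], labels[i]] <- D[exemplarStates[i], labels[i]] + 1
  lab <- new("ModelLevel",
    A = list(list(list(D = D, E = NULL))),
    B = list(array(diag(K), c(K, K, 1L))),
    children = list(1L), R = 1L,
    nStates = K, nPaths = 1L)
  m@levels[[length(m@levels) + 1L]] <- lab
  m@labelLevel <- TRUE
  m@Dtop <- rep(1, K)
  m@Etop <- 1
  validObject(m)
  m
}

#' Expected-free-energy gate for model growth
#'
#' Scores adding a new latent cause (a fresh one-hot likelihood column) for an
#' observation against explaining it with the current columns. \code{deltaF}
#' compares the variational (one-hot posterior) evidence bounds of the
#' augmented and parent models; \code{deltaG} compares their negative
#' parameter expected free energies (mutual information under flat
#' preferences). Growth is accepted iff \code{deltaF + deltaG > 0}.
#'
#' @param a likelihood count matrix (outcomes x states) of the parent model.
#' @param o one-hot (or soft) outcome vector to be explained.
#' @param floor count floor applied before normalization.
#' @return list with \code{deltaF}, \code{deltaG}, \code{accepted}.
#' @export
gateGrowth <- function(a, o, floor = 1 / 32) {
  stopifnot(nrow(a) == length(o))
  S <- ncol(a)
  af <- a + floor
  evidenceBound <- function(af) {
    S <- ncol(af)
    p <- normalizeCounts(af)
    max(log(1 / S) + log(colSums(p * o)))
  }
  aug <- cbind(af, o + floor)
  dF <- evidenceBound(aug) - evidenceBound(af)
  dG <- mutualInformation(aug) - mutualInformation(af)
  list(deltaF = dF, deltaG = dG, accepted = (dF + dG) > 0)
}

#' Merge helper: all groups into one parent
#' @param ng number of child groups
#' @export
mergeAll <- function(ng) list(seq_len(ng))

#' Merge helper: 2x2 blocks of a row-major group grid
#' @param nbr,nbc grid rows and columns (must be even)
#' @export
gridMerge2x2 <- function(nbr, nbc) {
  if (nbr %% 2L || nbc %% 2L) stop("grid dimensions must be even for 2x2 merging")
  out <- list()
  for (bi in seq_len(nbr %/% 2L)) for (bj in seq_len(nbc %/% 2L)) {
    r <- 2L * bi - 1L; c <- 2L * bj - 1L
    out[[length(out) + 1L]] <- c((r - 1L) * nbc + c, (r - 1L) * nbc + c + 1L,
                                 r * nbc + c, r * nbc + c + 1L)
  }
  out
}
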