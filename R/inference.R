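# Model inversion. Within each segment (the R steps one parent step spans)
# the posterior over the trajectory and path is computed exactly per path
# slice (forward-backward), and the path posterior from the per-path
# evidence; these are the fixed points of the variational updates. Levels
# exchange messages on the separation-of-timescales schedule: a level
# completes R child segments per own step (up pass), and returns empirical
# priors over child initial states and paths (down pass).

# log( exp(lnM) %*% exp(V) ) with per-column shifts on V.
logMatProd <- function(lnM, V) {
  sh <- apply(V, 2L, max)
  sh[!is.finite(sh)] <- 0
  W <- exp(sweep(V, 2L, sh))
  out <- log(pmax(exp(lnM) %*% W, .Machine$double.xmin))
  sweep(out, 2L, sh, "+")
}

# Canonical soft observation stream from a DiscreteObservation (one-hot), or
# pass-through for an existing stream. A stream is a list with prob (list per
# group of list per variate of [alphabet x T] matrices; NULL variate matrix
# means missing throughout), R, breaks.
#' Convert an observation to a soft likelihood stream
#'
#' @param obs a DiscreteObservation.
#' @return a stream: list(prob, alphabet, R, breaks). Entries may then be
#'   blanked with \code{\link{maskStream}} to model imprecise observations.
#' @export
asStream <- function(obs) {
  if (!is(obs, "DiscreteObservation")) {
    if (is.list(obs) && !is.null(obs$prob)) return(obs)
    stop("obs must be a DiscreteObservation or a stream")
  }
  prob <- lapply(seq_along(obs@idx), function(g) {
    lapply(seq_along(obs@alphabet[[g]]), function(v) {
      a <- obs@alphabet[[g]][v]
      m <- matrix(0, a, ncol(obs@idx[[g]]))
      m[cbind(obs@idx[[g]][v, ], seq_len(ncol(m)))] <- 1
      m
    })
  })
  list(prob = prob, alphabet = obs@alphabet, R = obs@R, breaks = obs@breaks)
}

#' Blank out parts of a stream as imprecise
#'
#' Marks the given groups (for the given voxel-time steps) as missing: the
#' likelihood message becomes uniform, contributing nothing to inference.
#'
#' @param stream a stream from \code{\link{asStream}}.
#' @param groups integer vector of group indices to mask.
#' @param times integer vector of voxel-time indices (default: all).
#' @export
maskStream <- function(stream, groups, times = NULL) {
  for (g in groups) for (v in seq_along(stream$prob[[g]])) {
    m <- stream$prob[[g]][[v]]
    tt <- if (is.null(times)) seq_len(ncol(m)) else times
    m[, tt] <- 1 / nrow(m)
    stream$prob[[g]][[v]] <- m
  }
  stream
}

# Level-1 log-likelihood messages: for each group a [nStates x T] matrix.
# Uniform observation vectors contribute zero (imprecise outcomes).
level1LogLik <- function(m, stream) {
  lev <- m@levels[[1L]]
  eps <- m@floor
  lapply(seq_along(lev@A), function(g) {
    S <- lev@nStates[g]
    Tn <- ncol(stream$prob[[g]][[1L]])
    L <- matrix(0, S, Tn)
    for (v in seq_along(lev@A[[g]])) {
      lnA <- expectedLogFloored(lev@A[[g]][[v]]$D, eps)
      o <- stream$prob[[g]][[v]]
      rng <- apply(o, 2L, function(x) max(x) - min(x))
      informative <- rng > 1e-12
      if (any(informative))
        L[, informative] <- L[, informative] +
          crossprod(lnA, o[, informative, drop = FALSE])
    }
    L
  })
}

# Per-segment evidence table for one group: Z[i, p, seg] = log evidence of
# segment seg given initial state i and path p.
segmentEvidence <- function(L, lnB, R) {
  S <- nrow(L)
  P <- dim(lnB)[3L]
  Tn <- ncol(L)
  nSeg <- Tn %/% R
  if (R == 1L) {
    Z <- array(L[, seq_len(nSeg), drop = FALSE], c(S, 1L, nSeg))
    return(Z)
  }
  Z <- array(0, c(S, P, nSeg))
  t0 <- (seq_len(nSeg) - 1L) * R + 1L
  if (R == 2L) {
    Lnext <- L[, t0 + 1L, drop = FALSE]
    for (p in seq_len(P))
      Z[, p, ] <- L[, t0, drop = FALSE] + logMatProd(t(lnB[, , p]), Lnext)
    return(Z)
  }
  for (p in seq_len(P)) {
    for (sg in seq_len(nSeg)) {
      ts <- t0[sg]
      # W[j, i]: log evidence of steps ts..t given s_t = j, s_ts = i
      W <- matrix(-Inf, S, S)
      diag(W) <- L[, ts]
      for (tau in seq_len(R - 1L)) {
        W <- logMatProd(lnB[, , p], W) + L[, ts + tau]
      }
      Z[, p, sg] <- apply(W, 2L, logSumExp)
    }
  }
  Z
}

# Exact within-segment smoothing for one (group, segment): returns state
# marginals per step, path posterior and log evidence, given log prior
# messages over initial states (lnD) and paths (lnE).
segmentPosterior <- function(L, lnB, R, t0, lnD, lnE) {
  S <- nrow(L)
  P <- length(lnE)
  if (R == 1L) {
    lq <- lnD + L[, t0]
    z <- logSumExp(lq)
    return(list(qs = matrix(softmax(lq), S, 1L), qu = softmax(lnE), logZ = z))
  }
  qsP <- array(0, c(S, R, P))
  lz <- numeric(P)
  for (p in seq_len(P)) {
    fwd <- matrix(0, S, R)
    v <- lnD + L[, t0]
    fwd[, 1L] <- v
    for (tau in 2L:R) {
      v <- as.vector(logMatProd(lnB[, , p], matrix(v))) + L[, t0 + tau - 1L]
      fwd[, tau] <- v
    }
    lz[p] <- logSumExp(v)
    beta <- matrix(0, S, R)
    b <- rep(0, S)
    for (tau in (R - 1L):1L) {
      b <- as.vector(logMatProd(t(lnB[, , p]), matrix(b + L[, t0 + tau])))
      beta[, tau] <- b
    }
    for (tau in seq_len(R)) qsP[, tau, p] <- softmax(fwd[, tau] + beta[, tau])
  }
  lqu <- lnE + lz
  qu <- softmax(lqu)
  qs <- matrix(0, S, R)
  for (p in seq_len(P)) qs <- qs + qu[p] * qsP[, , p]
  list(qs = qs, qu = qu, logZ = logSumExp(lqu))
}

# combined (lnD[i] + lnE[p]) weight matrix over parent states: [K x S*P]
mapWeights <- function(lnD, lnE) {
  S <- nrow(lnD); K <- ncol(lnD)
  if (is.null(lnE)) return(t(lnD))
  P <- nrow(lnE)
  W <- matrix(0, K, S * P)
  for (p in seq_len(P))
    W[, (p - 1L) * S + seq_len(S)] <- t(lnD) + lnE[p, ]
  W
}

#' Invert a renormalizing generative model
#'
#' Runs the scheduled message passing: exact per-segment inversion at each
#' level feeding ascending likelihood messages to the level above, an exact
#' forward-backward pass over the top-level chain (per-step path slices,
#' episodes reset at breaks), and, optionally, a top-down pass returning
#' smoothed state/path expectations at every level.
#'
#' @param m an \linkS4class{RGModel}.
#' @param obs a \linkS4class{DiscreteObservation} or a stream from
#'   \code{\link{asStream}} (possibly masked).
#' @param downPass compute smoothed expectations at all levels (default TRUE;
#'   switch off for speed when only the top posterior is needed).
#' @return a \linkS4class{Posterior}.
#' @export
infer <- function(m, obs, downPass = TRUE) {
  stream <- asStream(obs)
  lev1 <- m@levels[[1L]]
  for (g in seq_along(lev1@A))
    for (v in seq_along(lev1@A[[g]]))
      if (nrow(stream$prob[[g]][[v]]) != nrow(lev1@A[[g]][[v]]$D))
        stop("model/observation alphabet mismatch")
  N <- length(m@levels)
  eps <- m@floor
  span <- temporalSpan(m)
  T1 <- ncol(stream$prob[[1L]][[1L]])
  if (T1 %% span != 0L) {  # pad with missing steps
    add <- span - T1 %% span
    for (g in seq_along(stream$prob)) for (v in seq_along(stream$prob[[g]])) {
      a <- nrow(stream$prob[[g]][[v]])
      stream$prob[[g]][[v]] <- cbind(stream$prob[[g]][[v]], matrix(1 / a, a, add))
    }
    T1 <- T1 + add
  }
  L <- vector("list", N)
  L[[1L]] <- level1LogLik(m, stream)
  Zs <- vector("list", N)     # evidence tables per level (by child group)
  for (n in seq_len(N - 1L)) {
    up <- m@levels[[n + 1L]]
    lev <- m@levels[[n]]
    R <- up@R
    Zs[[n]] <- lapply(seq_along(lev@A), function(g) {
      P <- if (R == 1L) 1L else dim(lev@B[[g]])[3L]
      lnB <- expectedLogFloored(lev@B[[g]], eps)
      segmentEvidence(L[[n]][[g]], lnB, R)
    })
    L[[n + 1L]] <- lapply(seq_along(up@A), function(G) {
      K <- up@nStates[G]
      nSeg <- dim(Zs[[n]][[up@children[[G]][1L]]])[3L]
      out <- matrix(0, K, nSeg)
      for (i in seq_along(up@children[[G]])) {
        ch <- up@children[[G]][i]
        Z <- Zs[[n]][[ch]]
        S <- dim(Z)[1L]; P <- dim(Z)[2L]
        lnD <- expectedLogFloored(up@A[[G]][[i]]$D, eps)
        E <- up@A[[G]][[i]]$E
        lnE <- if (is.null(E) || P == 1L) NULL else expectedLogFloored(E, eps)
        if (is.null(lnE) && P > 1L) Z <- array(apply(Z, c(1L, 3L), logSumExp) - log(P), c(S, 1L, dim(Z)[3L]))
        W <- mapWeights(lnD, lnE)  # K x S*Peff
        Zm <- matrix(Z, nrow = dim(Z)[1L] * dim(Z)[2L])
        out <- out + logMatProd(W, Zm)
      }
      out
    })
  }
  # top-level chain
  top <- m@levels[[N]]
  lnDtop <- as.vector(expectedLogFloored(matrix(m@Dtop), eps))
  lnEtop <- as.vector(expectedLogFloored(matrix(m@Etop), eps))
  lnB <- expectedLogFloored(top@B[[1L]], eps)
  S <- top@nStates[1L]; P <- top@nPaths[1L]
  Ltop <- L[[N]][[1L]]
  Tt <- ncol(Ltop)
  breaksTop <- unique((stream$breaks - 1L) %/% span + 1L)
  breaksTop <- breaksTop[breaksTop <= Tt]
  Mbar <- matrix(0, S, S)
  for (p in seq_len(P)) Mbar <- Mbar + exp(lnEtop[p]) * exp(lnB[, , p])
  Mbar <- pmax(Mbar, .Machine$double.xmin)
  lfwd <- matrix(0, S, Tt); lbwd <- matrix(0, S, Tt)
  logZ <- 0
  epStarts <- breaksTop
  epEnds <- c(breaksTop[-1L] - 1L, Tt)
  for (e in seq_along(epStarts)) {
    ts <- epStarts[e]:epEnds[e]
    v <- lnDtop + Ltop[, ts[1L]]
    lfwd[, ts[1L]] <- v
    if (length(ts) > 1L) for (t in ts[-1L]) {
      v <- as.vector(logMatProd(log(Mbar), matrix(v))) + Ltop[, t]
      lfwd[, t] <- v
    }
    logZ <- logZ + logSumExp(v)
    b <- rep(0, S)
    lbwd[, ts[length(ts)]] <- b
    if (length(ts) > 1L) for (t in rev(ts[-length(ts)])) {
      b <- as.vector(logMatProd(t(log(Mbar)), matrix(b + Ltop[, t + 1L])))
      lbwd[, t] <- b
    }
  }
  qTop <- matrix(0, S, Tt)
  for (t in seq_len(Tt)) qTop[, t] <- softmax(lfwd[, t] + lbwd[, t])
  # top path posterior per step (NA-free; last step of an episode keeps prior)
  qU <- matrix(rep(softmax(lnEtop), Tt), P, Tt)
  for (t in seq_len(Tt - 1L)) {
    if ((t + 1L) %in% breaksTop) next
    lw <- vapply(seq_len(P), function(p)
      lnEtop[p] + logSumExp(sweep(lnB[, , p], 2L, lfwd[, t], "+") +
                            (lbwd[, t + 1L] + Ltop[, t + 1L])), numeric(1L))
    qU[, t] <- softmax(lw)
  }
  sOut <- vector("list", N)
  uOut <- vector("list", N)
  Fout <- numeric(N)
  sOut[[N]] <- list(qTop)
  uOut[[N]] <- list(qU)
  Fout[N] <- -logZ
  if (downPass && N > 1L) {
    qAbove <- list(qTop)  # per group at level n+1
    for (n in (N - 1L):1L) {
      up <- m@levels[[n + 1L]]
      lev <- m@levels[[n]]
      R <- up@R
      ngn <- length(lev@A)
      nSeg <- ncol(qAbove[[1L]])
      sOut[[n]] <- vector("list", ngn)
      uOut[[n]] <- vector("list", ngn)
      Flev <- 0
      for (G in seq_along(up@A)) for (i in seq_along(up@children[[G]])) {
        ch <- up@children[[G]][i]
        Z <- Zs[[n]][[ch]]
        Sg <- dim(Z)[1L]; Pg <- dim(Z)[2L]
        lnD <- expectedLogFloored(up@A[[G]][[i]]$D, eps)
        E <- up@A[[G]][[i]]$E
        lnE <- if (is.null(E) || Pg == 1L) matrix(log(1 / Pg), Pg, up@nStates[G]) else expectedLogFloored(E, eps)
        lnBg <- expectedLogFloored(lev@B[[ch]], eps)
        qs <- matrix(0, Sg, nSeg * R)
        qu <- matrix(0, max(Pg, 1L), nSeg)
        for (sg in seq_len(nSeg)) {
          qk <- qAbove[[G]][, sg]
          # posterior predictive prior messages from the parent posterior
          lnDmsg <- log(pmax(exp(lnD) %*% qk, .Machine$double.xmin))
          lnEmsg <- log(pmax(exp(lnE) %*% qk, .Machine$double.xmin))
          sp <- segmentPosterior(L[[n]][[ch]], lnBg, R, (sg - 1L) * R + 1L,
                                 as.vector(lnDmsg), as.vector(lnEmsg))
          qs[, (sg - 1L) * R + seq_len(R)] <- sp$qs
          qu[, sg] <- sp$qu
          Flev <- Flev - sp$logZ
        }
        sOut[[n]][[ch]] <- qs
        uOut[[n]][[ch]] <- qu
      }
      Fout[n] <- Flev
      qAbove <- sOut[[n]]
    }
  }
  new("Posterior", s = sOut, u = uOut, F = Fout, logZ = logZ,
      topSeq = apply(qTop, 2L, which.max))
}

#' Mean-field fixed-point sweeps for one segment
#'
#' The iterative counterpart of the exact per-segment inversion: categorical
#' expectations over each time step's state and over the path are updated in
#' turn as softmax functions of the summed log-domain messages (likelihood,
#' forward/backward transition, and prior messages). Returns the expectation
#' trajectory and the mean-field free energy after every sweep, which is
#' non-increasing.
#'
#' @param L log-likelihood matrix (states x R).
#' @param lnB log transition tensor (states x states x paths).
#' @param lnD,lnE log prior messages over initial states and paths.
#' @param nSweeps maximum sweeps (default 16).
#' @param tol stop when |dF| < tol (default 1e-4 nats).
#' @param init optional list(qs, qu) initial expectations.
#' @return list(qs, qu, F = free-energy trace).
#' @export
vmpFixedPoint <- function(L, lnB, lnD, lnE, nSweeps = 16L, tol = 1e-4,
                          init = NULL) {
  if (any(!is.finite(L))) stop("numerical guard: non-finite message")
  S <- nrow(L); R <- ncol(L); P <- length(lnE)
  qs <- if (is.null(init)) matrix(1 / S, S, R) else init$qs
  qu <- if (is.null(init)) rep(1 / P, P) else init$qu
  Bq <- function() {  # E_q(u) ln B message matrix
    M <- matrix(0, S, S)
    for (p in seq_len(P)) M <- M + qu[p] * lnB[, , p]
    M
  }
  Fmf <- function() {
    ent <- sum(qs * log(pmax(qs, 1e-300))) + sum(qu * log(pmax(qu, 1e-300)))
    en <- sum(qs[, 1L] * lnD) + sum(qu * lnE) + sum(qs * L)
    if (R > 1L) for (tau in seq_len(R - 1L))
      en <- en + sum(qs[, tau + 1L] * (Bq() %*% qs[, tau]))
    ent - en
  }
  Ftrace <- Fmf()
  for (sw in seq_len(nSweeps)) {
    for (tau in seq_len(R)) {
      v <- L[, tau]
      if (tau == 1L) v <- v + lnD
      M <- Bq()
      if (tau > 1L) v <- v + as.vector(M %*% qs[, tau - 1L])
      if (tau < R) v <- v + as.vector(crossprod(M, qs[, tau + 1L]))
      qs[, tau] <- softmax(v)
    }
    lv <- lnE
    if (R > 1L) for (p in seq_len(P)) for (tau in seq_len(R - 1L))
      lv[p] <- lv[p] + sum(qs[, tau + 1L] * (lnB[, , p] %*% qs[, tau]))
    qu <- softmax(lv)
    Fnew <- Fmf()
    Ftrace <- c(Ftrace, Fnew)
    if (abs(Ftrace[length(Ftrace) - 1L] - Fnew) < tol) break
  }
  list(qs = qs, qu = qu, F = Ftrace)
}

# -- generation ---------------------------------------------------------------

pickIndex <- function(w, mode) {
  if (sum(w) <= 0) w <- rep(1, length(w))
  if (mode == "sample") sample.int(length(w), 1L, prob = w) else which.max(w)
}

#' Generate observations top-down
#'
#' Expands a top-level trajectory recursively: each state emits its
#' children's initial states (D) and paths (E); within-segment transitions
#' are applied R-1 times per level. Deterministic under one-hot tensors in
#' \code{"argmax"} mode; \code{"sample"} mode draws from the normalized
#' (floored) tensors and is reproducible under a seed.
#'
#' @param m an RGModel.
#' @param topState initial top state (ignored when \code{topSeq} given).
#' @param horizon number of top-level steps to generate.
#' @param topSeq optional explicit top trajectory.
#' @param mode "argmax" or "sample".
#' @param seed optional integer seed for sampling.
#' @return list with \code{obs} (DiscreteObservation), \code{top} (trajectory),
#'   \code{frames} (decoded array if the model carries a frontend).
#' @export
generateFrom <- function(m, topState = 1L, horizon = 1L, topSeq = NULL,
                         mode = c("argmax", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  N <- length(m@levels)
  top <- m@levels[[N]]
  S <- top@nStates[1L]; P <- top@nPaths[1L]
  if (is.null(topSeq)) {
    if (topState < 1L || topState > S) stop("invalid top state")
    B <- normalizeCounts(floorCounts(top@B[[1L]], m@floor))
    Epr <- m@Etop / sum(m@Etop)
    topSeq <- integer(horizon)
    topSeq[1L] <- topState
    if (horizon > 1L) for (t in 2L:horizon) {
      s <- topSeq[t - 1L]
      wp <- vapply(seq_len(P), function(p) Epr[p] * max(top@B[[1L]][, s, p]), numeric(1L))
      p <- pickIndex(wp, mode)
      topSeq[t] <- pickIndex(B[, s, p], mode)
    }
  }
  seqs <- list(topSeq)   # per group at current level
  for (n in N:2L) {
    lev <- m@levels[[n]]
    below <- m@levels[[n - 1L]]
    R <- lev@R
    nChild <- length(unlist(lev@children))
    childSeqs <- vector("list", nChild)
    for (G in seq_along(lev@A)) {
      sG <- seqs[[G]]
      for (i in seq_along(lev@children[[G]])) {
        ch <- lev@children[[G]][i]
        D <- normalizeCounts(floorCounts(lev@A[[G]][[i]]$D, m@floor))
        E <- lev@A[[G]][[i]]$E
        En <- if (is.null(E)) NULL else normalizeCounts(floorCounts(E, m@floor))
        Bc <- normalizeCounts(floorCounts(below@B[[ch]], m@floor))
        out <- integer(length(sG) * R)
        for (sg in seq_along(sG)) {
          k <- sG[sg]
          s <- pickIndex(D[, k], mode)
          p <- if (is.null(En)) 1L else pickIndex(En[, k], mode)
          out[(sg - 1L) * R + 1L] <- s
          if (R > 1L) for (tau in 2L:R) {
            s <- pickIndex(Bc[, s, p], mode)
            out[(sg - 1L) * R + tau] <- s
          }
        }
        childSeqs[[ch]] <- out
      }
    }
    seqs <- childSeqs
  }
  # level-1 states -> variate indices
  lev1 <- m@levels[[1L]]
  idx <- vector("list", length(lev1@A))
  alphabet <- vector("list", length(lev1@A))
  for (g in seq_along(lev1@A)) {
    Tn <- length(seqs[[g]])
    nv <- length(lev1@A[[g]])
    mM <- matrix(0L, nv, Tn)
    for (v in seq_len(nv)) {
      col <- apply(lev1@A[[g]][[v]]$D, 2L, which.max)
      mM[v, ] <- col[seqs[[g]]]
    }
    idx[[g]] <- mM
    alphabet[[g]] <- vapply(lev1@A[[g]], function(x) nrow(x$D), integer(1L))
  }
  R1 <- if (length(m@partition)) m@partition[[1L]]@R else 1L
  obs <- new("DiscreteObservation", idx = idx, alphabet = alphabet,
             R = R1, breaks = 1L)
  frames <- NULL
  if (length(m@codecs) && length(m@partition))
    frames <- decodeFrames(obs, m@partition[[1L]], m@codecs)
  list(obs = obs, top = topSeq, frames = frames)
}

#' Classify observations under a label-level model
#'
#' Scores each episode by the posterior over classes at the label level and
#' by its evidence lower bound; episodes below the Occam threshold are marked
#' unclassifiable rather than forced into a class.
#'
#' @param m an RGModel with a label level.
#' @param obs a DiscreteObservation (episodes given by its breaks).
#' @param occamThreshold ELBO threshold in nats (default -Inf: accept all).
#' @return list with \code{posterior} (classes x episodes), \code{class}
#'   (MAP labels), \code{elbo} (per episode), \code{accepted}.
#' @export
classify <- function(m, obs, occamThreshold = -Inf) {
  if (!m@labelLevel) stop("model has no label level")
  stream <- asStream(obs)
  Tn <- ncol(stream$prob[[1L]][[1L]])
  eps <- c(stream$breaks, Tn + 1L)
  K <- m@levels[[length(m@levels)]]@nStates[1L]
  nEp <- length(stream$breaks)
  post <- matrix(0, K, nEp)
  el <- numeric(nEp)
  for (e in seq_len(nEp)) {
    ts <- eps[e]:(eps[e + 1L] - 1L)
    sub <- list(prob = lapply(stream$prob, function(gs)
      lapply(gs, function(mm) mm[, ts, drop = FALSE])),
      alphabet = stream$alphabet, R = stream$R, breaks = 1L)
    p <- infer(m, sub, downPass = FALSE)
    post[, e] <- p@s[[length(m@levels)]][[1L]][, 1L]
    el[e] <- p@logZ
  }
  list(posterior = post, class = apply(post, 2L, which.max), elbo = el,
       accepted = el > occamThreshold)
}

#' Pattern completion under partial observations
#'
#' Infers the posterior from a partially observed (masked) stream and returns
#' the posterior predictive over every first-level outcome, filling in the
#' missing groups/steps from the top-down messages.
#'
#' @param m an RGModel.
#' @param stream a stream from \code{\link{asStream}}, possibly masked; an
#'   all-missing stream returns the prior predictive.
#' @return list with \code{post} (Posterior), \code{predProb} (per group,
#'   per variate predictive matrices), \code{obs} (MAP DiscreteObservation),
#'   \code{frames} (decoded, when the model has a frontend).
#' @export
completeSequence <- function(m, stream) {
  stream <- asStream(stream)
  post <- infer(m, stream, downPass = TRUE)
  lev1 <- m@levels[[1L]]
  predProb <- vector("list", length(lev1@A))
  idx <- vector("list", length(lev1@A))
  alphabet <- vector("list", length(lev1@A))
  for (g in seq_along(lev1@A)) {
    qs <- post@s[[1L]][[g]]
    predProb[[g]] <- lapply(seq_along(lev1@A[[g]]), function(v) {
      An <- normalizeCounts(floorCounts(lev1@A[[g]][[v]]$D, m@floor))
      An %*% qs
    })
    nv <- length(lev1@A[[g]])
    idx[[g]] <- do.call(rbind, lapply(seq_len(nv), function(v)
      apply(predProb[[g]][[v]], 2L, which.max)))
    alphabet[[g]] <- vapply(lev1@A[[g]], function(x) nrow(x$D), integer(1L))
  }
  R1 <- if (length(m@partition)) m@partition[[1L]]@R else 1L
  obsOut <- new("DiscreteObservation", idx = idx, alphabet = alphabet,
                R = R1, breaks = 1L)
  frames <- NULL
  if (length(m@codecs) && length(m@partition))
    frames <- decodeFrames(obsOut, m@partition[[1L]], m@codecs)
  list(post = post, predProb = predProb, obs = obsOut, frames = frames)
}
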