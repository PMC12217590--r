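# Expert play from a structure-learned event model. The agent recognizes the
# current event through the action-independent content of its observations
# (the ball; the paddle row reports only the consequences of its own action),
# selects the next event on a path to reward through the inductively
# constrained prior, and acts so the paddle realizes the predicted positions.
# When execution diverges (shaky hand) or an event has no recorded
# continuation, the agent waits - emitting the stay action and sliding its
# event clock - until it recognizes an event inside the attracting set, then
# resumes expert play. Because training segments all terminate in a hit,
# every recognized event's predictions lead to a hit.

# action-independent content key: ball cells only (paddle row blanked)
ballKeyOf <- function(grids) {
  paste(vapply(grids, function(g) {
    g[GRID_H, ] <- CELL_BG
    g[g != CELL_BALL] <- CELL_BG
    paste(which(g == CELL_BALL), collapse = ".")
  }, character(1L)), collapse = "|")
}

#' Build a playing agent from a learned model and its training set
#'
#' Computes, from the training observation: per-event paddle trajectories,
#' the ball-content recognition table, the rewarded event set, the
#' reachability map, continuation lengths, and the chain starting points.
#'
#' @param m an RGModel learned from \code{train$obs}.
#' @param train output of \code{\link{trainingObservation}}.
#' @return agent list.
#' @export
makeAgent <- function(m, train) {
  cs <- compressSequence(m, train$obs)
  top <- cs$top
  span <- temporalSpan(m)
  N <- length(m@levels)
  S <- m@levels[[N]]@nStates[1L]
  nEv <- length(top)
  rewarded <- logical(S)
  paddle <- matrix(NA_integer_, span, S)
  keys <- character(S)
  for (e in seq_len(nEv)) {
    w <- ((e - 1L) * span + 1L):(e * span)
    k <- top[e]
    if (any(train$rewards[w])) rewarded[k] <- TRUE
    if (is.na(paddle[1L, k])) {
      paddle[, k] <- vapply(w, function(t)
        which(train$frames[[t]][GRID_H, ] == CELL_PM), integer(1L))
      keys[k] <- ballKeyOf(train$frames[w])
    }
  }
  B <- m@levels[[N]]@B[[1L]]
  reach <- inductiveReachability(B, which(rewarded))
  outDeg <- vapply(seq_len(S), function(s)
    sum(apply(B[, s, , drop = FALSE], 3L, max) > 0), integer(1L))
  edge <- matrix(FALSE, S, S)
  for (p in seq_len(dim(B)[3L])) edge <- edge | (t(B[, , p]) > 0)
  walk <- rep(0, S)
  for (k in seq_len(S)) {
    nxt <- ifelse(edge, matrix(walk, S, S, byrow = TRUE), -Inf)
    w2 <- ifelse(outDeg > 0, 1 + apply(nxt, 1L, max), 0)
    if (identical(w2, walk)) break
    walk <- w2
  }
  keyEvents <- split(seq_len(S), keys)
  starts <- lapply(seq_along(train$obs@breaks), function(i)
    list(state = train$starts[[i]],
         event = top[(train$obs@breaks[i] - 1L) %/% span + 1L]))
  list(model = m, span = span, rewarded = which(rewarded), reach = reach,
       paddle = paddle, keyEvents = keyEvents, outDeg = outDeg, walk = walk,
       starts = starts, B = B)
}

# events whose action-independent content matches the window, best
# continuation first; integer(0) when the content is unknown
matchEvents <- function(agent, grids) {
  ev <- agent$keyEvents[[ballKeyOf(grids)]]
  if (is.null(ev)) return(integer(0))
  ev[order(-agent$walk[ev], -as.integer(is.finite(agent$reach$steps[ev])))]
}

# next event via the inductively constrained path prior, preferring
# successors with long recorded continuations; NA when cur dead-ends.
chooseSuccessor <- function(agent, cur) {
  B <- agent$B
  P <- dim(B)[3L]
  succ <- rep(NA_integer_, P)
  for (p in seq_len(P)) {
    col <- B[, cur, p]
    if (max(col) > 0) succ[p] <- which.max(col)
  }
  ok <- which(!is.na(succ))
  if (length(ok) == 0L) return(NA_integer_)
  reachOK <- ok[is.finite(agent$reach$steps[succ[ok]])]
  if (length(reachOK)) ok <- reachOK
  score <- agent$walk[succ[ok]]
  prior <- suppressWarnings(
    planNextEvent(B, cur, agent$reach, Etop = agent$model@Etop))
  succ[ok[order(-score, -prior[ok])][1L]]
}

#' Play an episode under active inference
#'
#' Alternates between locked expert play (realize the chosen next event's
#' paddle trajectory, then confirm the event by its action-independent
#' content) and waiting recovery (stay, sliding the event clock one frame at
#' a time until a recognizable event inside the attracting set appears).
#' Optionally accumulates Dirichlet counts along recognized events
#' (continual learning) and records the per-event ELBO at every level.
#'
#' @param agent from \code{\link{makeAgent}}.
#' @param nSteps total environment steps to play.
#' @param stickyP shaky-hand probability (sample from the action posterior
#'   instead of taking its mode).
#' @param seed RNG seed (action sampling).
#' @param learn accumulate likelihood counts along confirmed events.
#' @param recordLevels also record the per-level free energies (slower:
#'   requires the top-down pass at every window).
#' @return list with \code{rewards}, \code{misses}, \code{actions},
#'   \code{elbo} (total per completed window), \code{elboLevels},
#'   \code{events} (confirmed top states, NA while waiting), \code{model}.
#' @export
playEpisode <- function(agent, nSteps = 512L, stickyP = 0, seed = 1L,
                        learn = FALSE, recordLevels = FALSE) {
  set.seed(seed)
  if (length(agent$starts) == 0L) stop("no starting event available")
  m <- agent$model
  span <- agent$span
  alphabet <- nrow(m@levels[[1L]]@A[[1L]][[1L]]$D)
  st <- agent$starts[[1L]]$state
  cur <- agent$starts[[1L]]$event
  rewards <- logical(nSteps); misses <- logical(nSteps); actions <- integer(nSteps)
  elbo <- numeric(0); elboLevels <- NULL; events <- integer(0)
  buf <- vector("list", 0)
  locked <- TRUE
  target <- cur          # event whose paddle trajectory is being realized
  tau <- 0L              # frames realized of the target window
  t <- 0L
  while (t < nSteps) {
    t <- t + 1L
    if (locked) {
      tau <- tau + 1L
      sel <- selectAction(agent$paddle[tau, target], st$paddle, stickyP = stickyP)
      act <- sel$action
    } else {
      act <- 0L          # wait for a recognizable event
    }
    st <- gameStep(st, act)
    actions[t] <- act
    rewards[t] <- st$reward
    misses[t] <- st$miss
    buf <- c(buf, list(renderGrid(st)))
    if (length(buf) > span) buf <- buf[-1L]
    if (locked && tau == span) {
      # window complete: confirm by action-independent content
      cand <- matchEvents(agent, buf)
      obsEv <- gridObservation(buf, alphabet = alphabet)
      post <- infer(m, maskPaddleRow(asStream(obsEv)), downPass = recordLevels)
      elbo <- c(elbo, post@logZ)
      if (recordLevels) elboLevels <- cbind(elboLevels, -post@F)
      if (length(cand)) {
        cur <- cand[1L]
        events <- c(events, cur)
        if (learn) m <- tryCatch(accumulateCounts(m, obsEv),
                                 error = function(err) m)
        nxt <- chooseSuccessor(agent, cur)
        if (is.na(nxt)) { locked <- FALSE } else { target <- nxt; tau <- 0L }
      } else {
        events <- c(events, NA_integer_)
        locked <- FALSE
      }
    } else if (!locked && length(buf) == span) {
      cand <- matchEvents(agent, buf)
      cand <- cand[agent$outDeg[cand] > 0]
      if (length(cand)) {
        cur <- cand[1L]
        nxt <- chooseSuccessor(agent, cur)
        if (!is.na(nxt)) {
          locked <- TRUE; target <- nxt; tau <- 0L
        }
      }
    }
  }
  list(rewards = rewards, misses = misses, actions = actions, elbo = elbo,
       elboLevels = elboLevels, events = events, model = m)
}

# mask the paddle row of a grid-observation stream (one group per cell,
# row-major over a 9 x 12 grid)
maskPaddleRow <- function(stream) {
  ng <- length(stream$prob)
  W <- GRID_W
  H <- ng %/% W
  maskStream(stream, which((seq_len(ng) - 1L) %/% W + 1L == H))
}

# Accumulate unit Dirichlet counts along the recognized branch of an
# observed (single-episode) window.
accumulateCounts <- function(m, obs) {
  cs <- compressSequence(m, obs)
  N <- length(m@levels)
  lev1 <- m@levels[[1L]]
  for (g in seq_along(lev1@A)) {
    sseq <- cs$states[[1L]][[g]]
    for (v in seq_along(lev1@A[[g]])) {
      o <- obs@idx[[g]][v, ]
      for (t in seq_along(sseq))
        lev1@A[[g]][[v]]$D[o[t], sseq[t]] <- lev1@A[[g]][[v]]$D[o[t], sseq[t]] + 1
    }
  }
  m@levels[[1L]] <- lev1
  for (n in 2L:N) {
    lev <- m@levels[[n]]
    R <- lev@R
    for (G in seq_along(lev@A)) {
      kseq <- cs$states[[n]][[G]]
      for (i in seq_along(lev@children[[G]])) {
        ch <- lev@children[[G]][i]
        iseq <- cs$states[[n - 1L]][[ch]]
        pseq <- cs$paths[[n - 1L]][[ch]]
        for (sg in seq_along(kseq)) {
          k <- kseq[sg]
          ini <- iseq[(sg - 1L) * R + 1L]
          lev@A[[G]][[i]]$D[ini, k] <- lev@A[[G]][[i]]$D[ini, k] + 1
          if (!is.null(lev@A[[G]][[i]]$E)) {
            p <- pseq[sg]
            lev@A[[G]][[i]]$E[p, k] <- lev@A[[G]][[i]]$E[p, k] + 1
          }
        }
      }
    }
    m@levels[[n]] <- lev
  }
  m
}
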