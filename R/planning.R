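# Planning as inference over the top-level event graph: expected free energy
# per controllable path slice (risk, ambiguity, novelty), inductive inference
# by backward reachability from rewarded events, and action selection that
# realizes the predicted outcomes in the controllable modality.

#' Expected free energy per path
#'
#' For each path slice of a transition tensor, computes the predictive
#' distribution over next states and outcomes and decomposes expected free
#' energy into risk (KL from predictive outcomes to preferences), ambiguity
#' (expected conditional outcome entropy) and novelty (the Dirichlet-count
#' information gain of the outcome mapping), with
#' \code{G = risk + ambiguity - novelty}.
#'
#' @param B transition count tensor (next state x state x path).
#' @param q current state expectation (vector summing to 1).
#' @param outcome outcome likelihood counts (outcomes x states); identity
#'   mapping if omitted (outcomes = states).
#' @param c preference counts over outcomes (default uniform).
#' @param floor count floor for normalization.
#' @param riskCeiling cap (nats) applied where preferences put zero mass on
#'   a supported outcome.
#' @return data.frame with one row per path: risk, ambiguity, novelty, G.
#' @export
efePaths <- function(B, q, outcome = NULL, c = NULL, floor = 1 / 32,
                     riskCeiling = 32) {
  S <- dim(B)[2L]
  P <- dim(B)[3L]
  if (is.null(outcome)) outcome <- diag(S)
  K <- nrow(outcome)
  if (is.null(c)) c <- rep(1, K)
  On <- normalizeCounts(floorCounts(outcome, floor))
  Bn <- normalizeCounts(floorCounts(B, floor))
  cN <- c / sum(c)
  a <- floorCounts(outcome, floor)
  a0 <- rep(colSums(a), each = K)
  W <- 0.5 * (1 / a - 1 / a0)  # count-based novelty weights
  out <- data.frame(risk = numeric(P), ambiguity = numeric(P),
                    novelty = numeric(P), G = numeric(P))
  for (p in seq_len(P)) {
    qs1 <- as.vector(Bn[, , p] %*% q)
    qo <- as.vector(On %*% qs1)
    lr <- ifelse(qo > 0 & cN > 0, log(qo / cN), 0)
    lr[qo > 0 & cN == 0] <- riskCeiling
    if (any(qo > 0 & cN == 0))
      warning("zero preference mass on a supported outcome; risk clipped")
    risk <- min(sum(qo * lr), riskCeiling)
    amb <- -sum(qs1 * colSums(On * log(pmax(On, 1e-300))))
    nov <- sum(qs1 * colSums(On * W))
    out[p, ] <- c(risk, amb, nov, risk + amb - nov)
  }
  out
}

#' Inductive reachability of rewarded events
#'
#' Backward breadth-first iteration over the allowable transitions (any path
#' slice with normalized probability above the threshold): for every state,
#' the minimal number of events to reach a rewarded event, Inf when a reward
#' is precluded.
#'
#' @param B transition count tensor (next x current x path).
#' @param rewardedSet integer indices of rewarded states.
#' @param horizon maximum lookahead (default: number of states).
#' @param threshold normalized probability above which a transition counts as
#'   an allowable edge.
#' @return list with \code{steps} (numeric vector, 0 on rewardedSet),
#'   \code{rewarded}.
#' @export
inductiveReachability <- function(B, rewardedSet, horizon = NULL,
                                  threshold = 1e-3) {
  if (length(rewardedSet) == 0L) stop("rewardedSet must be nonempty")
  S <- dim(B)[2L]
  if (is.null(horizon)) horizon <- S
  Bn <- normalizeCounts(B)
  # edge[i, j]: allowable transition from i to j under some path
  edge <- matrix(FALSE, S, S)
  for (p in seq_len(dim(B)[3L]))
    edge <- edge | (t(Bn[, , p]) > threshold & t(B[, , p]) > 0)
  steps <- rep(Inf, S)
  steps[rewardedSet] <- 0
  for (k in seq_len(horizon)) {
    reachable <- which(is.finite(steps) & steps <= k - 1)
    cand <- which(rowSums(edge[, reachable, drop = FALSE]) > 0)
    newly <- setdiff(cand, which(is.finite(steps)))
    if (length(newly) == 0L) break
    steps[newly] <- k
  }
  list(steps = steps, rewarded = sort(unique(rewardedSet)))
}

#' Empirical prior over the next event's path
#'
#' Combines the expected free energy of each path slice with the inductive
#' constraint: paths leading into states that preclude a rewarded outcome
#' receive a large negative log-prior (-32 nats) rather than literal zero.
#' Falls back to the uniform prior (with a warning) when every successor is
#' precluded.
#'
#' @param B top-level transition counts.
#' @param q current top state expectation (vector or state index).
#' @param reach a reachability map from \code{\link{inductiveReachability}}.
#' @param Etop path prior counts.
#' @param efe optional data.frame from \code{\link{efePaths}} (G column).
#' @param threshold allowable-transition threshold.
#' @param penalty log-prior penalty for precluded successors.
#' @return numeric path prior (sums to 1).
#' @export
planNextEvent <- function(B, q, reach, Etop = NULL, efe = NULL,
                          threshold = 1e-3, penalty = -32) {
  S <- dim(B)[2L]; P <- dim(B)[3L]
  if (length(q) == 1L) q <- replace(rep(0, S), q, 1)
  if (is.null(Etop)) Etop <- rep(1, P)
  Bn <- normalizeCounts(B)
  lw <- log(Etop / sum(Etop))
  if (!is.null(efe)) lw <- lw - efe$G
  viable <- logical(P)
  for (p in seq_len(P)) {
    qs1 <- as.vector(Bn[, , p] %*% q)
    supp <- qs1 > threshold & as.vector(B[, , p] %*% q) > 0
    if (!any(supp)) { lw[p] <- lw[p] + penalty; next }
    if (all(!is.finite(reach$steps[supp]))) lw[p] <- lw[p] + penalty
    else viable[p] <- TRUE
  }
  if (!any(viable)) {
    warning("all successors precluded; falling back to the uniform path prior")
    return(rep(1, P) / P)
  }
  softmax(lw)
}

#' Select an action that realizes the predicted outcome
#'
#' Scores each candidate action by the predictive accuracy of its immediate
#' outcome in the controllable modality (here, the paddle position the
#' action would produce against the position the model predicts), forms the
#' softmax action posterior, and either takes its mode or, with probability
#' \code{stickyP} (the shaky-hand parameter), samples from it.
#'
#' @param predictedPaddle predicted paddle centre column.
#' @param paddle current paddle centre column.
#' @param stickyP probability of sampling instead of maximizing.
#' @param candidates candidate actions.
#' @param precision softmax precision on the (negative) cell mismatch.
#' @param gridW grid width for clamping.
#' @return list with \code{action} and \code{posterior}.
#' @export
selectAction <- function(predictedPaddle, paddle, stickyP = 0,
                         candidates = c(-1L, 0L, 1L), precision = 4,
                         gridW = 12L) {
  if (length(candidates) == 0L) stop("empty candidate action set")
  nxt <- pmax(2L, pmin(gridW - 1L, paddle + candidates))
  acc <- -abs(nxt - predictedPaddle) * precision
  post <- softmax(acc)
  a <- if (stickyP > 0 && stats::runif(1) < stickyP)
    candidates[sample.int(length(candidates), 1L, prob = post)]
  else candidates[which.max(post)]
  list(action = a, posterior = post)
}
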