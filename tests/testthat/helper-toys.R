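# Toy model builders and independent oracles used across the suite.

# Single-level (chain) model: one group, one outcome modality, explicit
# normalized tensors. With floor = 0 the model's expected logs are exact
# logs, so inference can be compared against brute-force enumeration.
toyChainModel <- function(A, B, Dtop = NULL, Etop = NULL, floor = 0) {
  S <- ncol(A)
  P <- dim(B)[3L]
  lev <- new("ModelLevel",
             A = list(list(list(D = A, E = NULL))),
             B = list(B), children = list(1L), R = 1L,
             nStates = S, nPaths = P)
  new("RGModel", levels = list(lev), partition = list(), codecs = list(),
      labelLevel = FALSE,
      Dtop = if (is.null(Dtop)) rep(1, S) else Dtop,
      Etop = if (is.null(Etop)) rep(1, P) else Etop,
      Cpref = list(), floor = floor, version = rgm:::RGM_FORMAT_VERSION)
}

toyObs <- function(symbols, alphabet, breaks = 1L) {
  new("DiscreteObservation", idx = list(matrix(symbols, 1L)),
      alphabet = list(as.integer(alphabet)), R = 1L,
      breaks = as.integer(breaks))
}

# Brute-force posterior marginals and evidence for a toy chain model with
# per-step paths, enumerating every joint configuration.
enumerateChain <- function(A, B, Dtop, Etop, obsIdx) {
  S <- ncol(A); P <- dim(B)[3L]; Tn <- length(obsIdx)
  Dn <- Dtop / sum(Dtop); En <- Etop / sum(Etop)
  states <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  paths <- if (Tn > 1L) as.matrix(expand.grid(rep(list(seq_len(P)), Tn - 1L)))
           else matrix(0L, 1L, 0L)
  margS <- matrix(0, S, Tn)
  margU <- matrix(0, P, max(Tn - 1L, 1L))
  Z <- 0
  for (i in seq_len(nrow(states))) for (j in seq_len(nrow(paths))) {
    s <- states[i, ]; u <- paths[j, ]
    pr <- Dn[s[1L]]
    if (Tn > 1L) for (t in seq_len(Tn - 1L))
      pr <- pr * En[u[t]] * B[s[t + 1L], s[t], u[t]]
    for (t in seq_len(Tn)) pr <- pr * A[obsIdx[t], s[t]]
    Z <- Z + pr
    for (t in seq_len(Tn)) margS[s[t], t] <- margS[s[t], t] + pr
    if (Tn > 1L) for (t in seq_len(Tn - 1L)) margU[u[t], t] <- margU[u[t], t] + pr
  }
  list(s = margS / Z, u = margU / Z, logZ = log(Z))
}

# Independent mutual information by exhaustive summation over a joint table.
bruteMI <- function(counts) {
  p <- counts / sum(counts)
  pr <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
  s
}

# Independent BFS distance-to-target on a digraph given an adjacency matrix
# edge[i, j] = TRUE for an arc i -> j.
bfsStepsToSet <- function(edge, targets) {
  n <- nrow(edge)
  d <- rep(Inf, n)
  d[targets] <- 0
  frontier <- targets
  k <- 0
  while (length(frontier)) {
    k <- k + 1
    nxt <- which(is.infinite(d) & rowSums(edge[, frontier, drop = FALSE]) > 0)
    if (!length(nxt)) break
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

# deterministic symbolic observation over ng groups with small alphabets
randomSymbolObs <- function(ng, alphabet, Tn, seed, breaks = 1L) {
  set.seed(seed)
  idx <- lapply(seq_len(ng), function(g)
    matrix(sample.int(alphabet, Tn, replace = TRUE), 1L, Tn))
  new("DiscreteObservation", idx = idx,
      alphabet = rep(list(as.integer(alphabet)), ng), R = 1L,
      breaks = as.integer(breaks))
}
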