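# Active learning of Dirichlet likelihoods. Count updates are treated as
# actions scored by the expected free energy of the parameters: the mutual
# information the tensor encodes, minus the expected cost under outcome
# preferences. Bayesian model reduction evaluates simpler priors post hoc
# with log-beta algebra.

#' Expected free energy of Dirichlet parameters
#'
#' \eqn{G(a) = -MI(a) - cost(a, c)}: the negative mutual information between
#' outcomes and (joint) parent states encoded by the counts, minus the
#' expected preference satisfaction. The cost term uses the digamma
#' expectation of the preference counts and is measured relative to flat
#' preferences, so uniform \code{c} gives \eqn{G = -MI} exactly.
#'
#' Two routes are available: \code{method = "counts"} evaluates the
#' count-algebra expression (sums of \eqn{a\log a} over the tensor and its
#' margins); \code{method = "direct"} normalizes the joint and sums
#' \eqn{p \log(p / p_{row} p_{col})}. They agree to numerical precision and
#' serve as mutual cross-checks.
#'
#' @param a count array (outcome axis first).
#' @param c preference counts over outcomes (default uniform).
#' @param method "counts" or "direct".
#' @return expected free energy in nats.
#' @export
parameterEFE <- function(a, c = NULL, method = c("direct", "counts")) {
  method <- match.arg(method)
  a <- as.array(a)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  if (!is.null(c) && length(c) != d[1L])
    stop("preference counts must match the outcome axis")
  mi <- if (method == "direct") {
    mutualInformation(a)
  } else {
    # count algebra: MI = [sum a log a - sum rowsum log rowsum
    #                      - sum colsum log colsum + N log N] / N
    N <- sum(m)
    xlx <- function(x) sum(x[x > 0] * log(x[x > 0]))
    if (nrow(m) == 1L || ncol(m) == 1L) 0
    else max((xlx(m) - xlx(rowSums(m)) - xlx(colSums(m)) + N * log(N)) / N, 0)
  }
  cost <- 0
  if (!is.null(c)) {
    po <- rowSums(m) / sum(m)
    psi <- digamma(c) - digamma(sum(c))
    cost <- sum(po * psi) - mean(psi)
  }
  -mi - cost
}

#' Propose a gated Dirichlet count update
#'
#' Forms the increment \eqn{\Delta a} as the outer product of the outcome
#' expectation and the parent-state expectations (unit mass per modality per
#' time step), scores the parameter expected free energy without (G0) and
#' with (G1) the update, and commits the Bayesian model average
#' \eqn{a \leftarrow a + P(u_1)\,\Delta a} with
#' \eqn{P(u_1) = \sigma(-\alpha G)_1}. As \eqn{\alpha \to \infty} the average
#' becomes model selection.
#'
#' @param a count matrix (outcomes x parent states).
#' @param outcome outcome expectation (sums to 1).
#' @param parent parent-state expectation (sums to 1); for several parent
#'   factors pass the Kronecker product.
#' @param c preference counts (default uniform).
#' @param alpha non-negative precision hyperprior.
#' @param commit apply the averaged update and return the new counts.
#' @return list with \code{delta}, \code{G0}, \code{G1}, \code{pAccept}, and
#'   (if commit) \code{a}.
#' @export
proposeUpdate <- function(a, outcome, parent, c = NULL, alpha = 512,
                          commit = TRUE) {
  if (alpha < 0) stop("alpha must be non-negative")
  delta <- outer(outcome, parent)
  G0 <- parameterEFE(a, c)
  G1 <- parameterEFE(a + delta, c)
  p <- if (is.infinite(alpha)) as.numeric(G1 < G0) else softmax(-alpha * c(G0, G1))[2L]
  out <- list(delta = delta, G0 = G0, G1 = G1, pAccept = p)
  if (commit) out$a <- a + p * delta
  out
}

#' Active learning over an observation stream
#'
#' Assimilates episodes one at a time: each episode is inverted under the
#' current model, and for every level the likelihood-count increments implied
#' by the posterior expectations are proposed and committed only when the
#' parameter expected free energy of the committed tensor does not increase
#' (so the mutual-information trace is non-decreasing by construction).
#' Convergence is declared when the windowed mean MI gain falls below
#' \code{tol}.
#'
#' @param m an RGModel (structure already learned).
#' @param obs a DiscreteObservation whose episodes (breaks) are the
#'   exemplars.
#' @param alpha precision of the update prior (default 512).
#' @param c optional list of preference counts per top outcome (default flat).
#' @param tol convergence tolerance on the windowed MI gain (nats).
#' @param window exemplar window for the convergence test.
#' @return list with \code{model}, \code{mi} (trace of top-level MI per
#'   exemplar), \code{elbo} (per exemplar), \code{converged},
#'   \code{nAssimilated}.
#' @export
activeLearn <- function(m, obs, alpha = 512, c = NULL, tol = 1e-3,
                        window = 32L) {
  stream <- asStream(obs)
  Tn <- ncol(stream$prob[[1L]][[1L]])
  epb <- c(stream$breaks, Tn + 1L)
  nEp <- length(stream$breaks)
  N <- length(m@levels)
  miTrace <- numeric(nEp)
  elboTrace <- numeric(nEp)
  topA <- function(mm) mm@levels[[N]]@A[[1L]][[1L]]$D
  for (e in seq_len(nEp)) {
    ts <- epb[e]:(epb[e + 1L] - 1L)
    sub <- list(prob = lapply(stream$prob, function(gs)
      lapply(gs, function(x) x[, ts, drop = FALSE])),
      alphabet = stream$alphabet, R = stream$R, breaks = 1L)
    post <- infer(m, sub, downPass = TRUE)
    elboTrace[e] <- post@logZ
    # bottom-up committed updates of the inter-level likelihood mappings
    for (n in 2L:N) {
      lev <- m@levels[[n]]
      qPar <- post@s[[n]]
      for (G in seq_along(lev@A)) for (i in seq_along(lev@children[[G]])) {
        ch <- lev@children[[G]][i]
        qInit <- post@s[[n - 1L]][[ch]]
        qPath <- post@u[[n - 1L]][[ch]]
        R <- lev@R
        nSeg <- ncol(qPar[[G]])
        gatedCommit <- function(a, outcome, parent) {
          pr <- proposeUpdate(a + m@floor, outcome, parent, c = NULL,
                              alpha = alpha, commit = FALSE)
          cand <- a + pr$pAccept * pr$delta
          if (parameterEFE(cand + m@floor) <= pr$G0 + 1e-12) cand else a
        }
        for (sg in seq_len(nSeg)) {
          lev@A[[G]][[i]]$D <- gatedCommit(lev@A[[G]][[i]]$D,
                                           qInit[, (sg - 1L) * R + 1L],
                                           qPar[[G]][, sg])
          E <- lev@A[[G]][[i]]$E
          if (!is.null(E) && nrow(E) > 1L)
            lev@A[[G]][[i]]$E <- gatedCommit(E, qPath[, sg], qPar[[G]][, sg])
        }
      }
      m@levels[[n]] <- lev
    }
    miTrace[e] <- mutualInformation(topA(m) + m@floor)
    if (e >= 2L * window) {
      recent <- mean(miTrace[(e - window + 1L):e])
      before <- mean(miTrace[(e - 2L * window + 1L):(e - window)])
      if (recent - before < tol)
        return(list(model = m, mi = miTrace[seq_len(e)],
                    elbo = elboTrace[seq_len(e)], converged = TRUE,
                    nAssimilated = e))
    }
  }
  list(model = m, mi = miTrace, elbo = elboTrace, converged = FALSE,
       nAssimilated = nEp)
}

#' Bayesian model reduction for Dirichlet counts
#'
#' Evaluates the change in free energy of replacing the prior counts
#' \code{prior} by the reduced prior \code{reduced}, given the posterior
#' counts \code{posterior}, via
#' \eqn{\Delta F = \ln B(\bar a) + \ln B(a') - \ln B(a) - \ln B(\bar a + a' - a)},
#' and returns the implied reduced posterior \eqn{\bar a' = \bar a + a' - a}.
#'
#' @param posterior,prior,reduced positive count vectors of equal length.
#' @return list with \code{deltaF} (nats) and \code{reducedPosterior}.
#' @export
bmrDeltaF <- function(posterior, prior, reduced) {
  stopifnot(length(posterior) == length(prior),
            length(prior) == length(reduced))
  rp <- posterior + reduced - prior
  if (any(rp <= 0)) stop("reduction infeasible: nonpositive reduced posterior count")
  dF <- logBeta(posterior) + logBeta(reduced) - logBeta(prior) - logBeta(rp)
  list(deltaF = dF, reducedPosterior = rp)
}
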