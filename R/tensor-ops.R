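# Elementary categorical/Dirichlet operators. Count tensors are plain numeric
# arrays with the outcome on the first axis; every remaining axis conditions.

#' Column-normalize a count tensor
#'
#' Normalizes over the outcome (first) axis so every conditioning column sums
#' to one. All-zero columns map to the uniform distribution, which keeps
#' generation defined for never-visited states.
#'
#' @param a numeric array (outcome axis first) with non-negative entries.
#' @return array of the same shape with columns on the outcome axis summing
#'   to 1.
#' @export
normalizeCounts <- function(a) {
  if (any(a < 0)) stop("invalid counts: negative entries")
  a <- as.array(a)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    m[, zero] <- 1 / d[1L]
    cs[zero] <- 1
  }
  m <- sweep(m, 2L, cs, "/")
  array(m, dim = d, dimnames = dimnames(a))
}

#' Expected log-probabilities under Dirichlet counts
#'
#' Applies \eqn{\psi(a) - \psi(\sum a)} column-wise over the outcome axis
#' (digamma of the counts minus digamma of the column sum): the expectation
#' of the log category probabilities under the Dirichlet with those counts.
#'
#' @param a numeric array of positive counts (add a floor first if needed).
#' @return array of the same shape; every entry is \eqn{\le 0}.
#' @export
expectedLog <- function(a) {
  if (any(a < 0)) stop("invalid counts: negative entries")
  a <- as.array(a)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  if (any(colSums(m) == 0)) stop("invalid counts: zero column (apply a floor first)")
  if (any(m == 0)) stop("invalid counts: zero entry (apply a floor first)")
  out <- digamma(m) - rep(digamma(colSums(m)), each = d[1L])
  array(pmin(out, 0), dim = d, dimnames = dimnames(a))
}

#' Softmax (normalized exponential)
#'
#' @param v numeric vector of finite log-weights.
#' @return positive vector summing to 1; invariant to additive shifts
#'   (the maximum is subtracted before exponentiation).
#' @export
softmax <- function(v) {
  w <- exp(v - max(v))
  w / sum(w)
}

#' Numerically safe log-sum-exp
#' @param v numeric vector (may contain -Inf).
#' @return log(sum(exp(v)))
#' @export
logSumExp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Mutual information encoded by a count tensor
#'
#' Treats the counts as an (unnormalized) joint distribution over the outcome
#' axis and all conditioning axes collapsed together, and returns the mutual
#' information (nats) between outcome and the joint parent state.
#'
#' @param a numeric array of non-negative counts with at least one positive
#'   entry.
#' @return mutual information in nats, in
#'   \eqn{[0, \min(\ln K_{out}, \ln K_{parents})]}.
#' @export
mutualInformation <- function(a) {
  if (any(a < 0)) stop("invalid counts: negative entries")
  a <- as.array(a)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  if (nrow(m) == 1L || ncol(m) == 1L) return(0)
  p <- m / sum(m)
  plogp <- function(x) sum(x[x > 0] * log(x[x > 0]))
  mi <- plogp(p) - plogp(rowSums(p)) - plogp(colSums(p))
  max(mi, 0)
}

#' Multivariate log-beta function
#'
#' \eqn{\ln\mathrm{B}(a) = \sum_i \ln\Gamma(a_i) - \ln\Gamma(\sum_i a_i)},
#' applied to a vector of Dirichlet counts.
#'
#' @param a positive numeric vector.
#' @return numeric(1)
#' @export
logBeta <- function(a) {
  if (any(a <= 0)) stop("log-beta requires positive counts")
  sum(lgamma(a)) - lgamma(sum(a))
}

# Apply the model floor to a count array (never mutates stored counts).
floorCounts <- function(a, eps) {
  if (eps <= 0) return(a)
  a + eps
}

# log of the column-normalized tensor, or the digamma expectation when a
# finite floor is in play. 'eps' is the model's count floor; eps == 0 means
# the infinite-count limit (plain log of the normalized columns, with -Inf
# replaced by a large negative constant for arithmetic safety).
expectedLogFloored <- function(a, eps, neg = -36) {
  if (eps > 0) return(expectedLog(floorCounts(a, eps)))
  p <- normalizeCounts(a)
  out <- log(p)
  out[!is.finite(out)] <- neg
  out
}
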