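test_that("expected free energy decomposes into risk, ambiguity and novelty", {
  S <- 3
  B <- array(0, c(S, S, 2))
  B[, , 1] <- diag(S); B[, , 2] <- diag(S)[, c(2, 3, 1)]
  # predictive equal to preference: risk vanishes; deterministic (one-hot)
  # likelihood: ambiguity vanishes
  O <- diag(S) * 1e8
  efe <- efePaths(B * 1e8, c(1, 0, 0), outcome = O,
                  c = c(1e6, 1e-6, 1e-6), floor = 1e-12)
  expect_equal(efe$risk[1L], 0, tolerance = 1e-4)  # path 1 stays at state 1
  expect_equal(efe$ambiguity, rep(0, 2), tolerance = 1e-5)
  # predictive equal to preference: zero risk even with sharp preferences
  c1 <- c(1e6, 1, 1)
  efe2 <- efePaths(B * 1e8, c(1, 0, 0), outcome = O, c = c1, floor = 1e-12)
  expect_lt(efe2$risk[1L], 1e-3)   # path 1 stays at state 1 = preferred
  expect_gt(efe2$risk[2L], 5)      # path 2 moves probability off the preference
  # 2-state 2-path toy against term-by-term hand enumeration
  B2 <- array(c(0.9, 0.1, 0.2, 0.8,  0.5, 0.5, 0.5, 0.5), c(2, 2, 2))
  O2 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2)
  q <- c(0.6, 0.4)
  cpref <- c(3, 1)
  eps <- 1 / 32
  hand <- lapply(1:2, function(p) {
    Bn <- normalizeCounts(B2[, , p] + eps)
    On <- normalizeCounts(O2 + eps)
    qs1 <- Bn %*% q
    qo <- On %*% qs1
    cN <- cpref / sum(cpref)
    risk <- sum(qo * log(qo / cN))
    amb <- -sum(qs1 * colSums(On * log(On)))
    a <- O2 + eps; a0 <- rep(colSums(a), each = 2)
    nov <- sum(qs1 * colSums(On * (0.5 * (1 / a - 1 / a0))))
    c(risk, amb, nov)
  })
  efe3 <- efePaths(B2, q, outcome = O2, c = cpref)
  for (p in 1:2) {
    expect_equal(efe3$risk[p], hand[[p]][1], tolerance = 1e-10)
    expect_equal(efe3$ambiguity[p], hand[[p]][2], tolerance = 1e-10)
    expect_equal(efe3$novelty[p], hand[[p]][3], tolerance = 1e-10)
    expect_equal(efe3$G[p], hand[[p]][1] + hand[[p]][2] - hand[[p]][3])
  }
})

test_that("inductive reachability equals an independent BFS on random digraphs", {
  # rewarded state itself: 0 steps; chain: distance
  chainB <- array(0, c(5, 5, 1))
  for (i in 1:4) chainB[i + 1, i, 1] <- 1
  r <- inductiveReachability(chainB, rewardedSet = 5)
  expect_equal(r$steps, c(4, 3, 2, 1, 0))
  expect_error(inductiveReachability(chainB, integer(0)), "nonempty")
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:64, 1)
    P <- sample(1:3, 1)
    B <- array(0, c(n, n, P))
    for (p in seq_len(P)) {
      src <- sample.int(n, n %/% 2)
      for (s in src) B[sample.int(n, 1), s, p] <- 1
    }
    targets <- sample.int(n, sample(1:3, 1))
    r <- inductiveReachability(B, targets)
    edge <- matrix(FALSE, n, n)
    for (p in seq_len(P)) edge <- edge | (t(B[, , p]) > 0)
    expect_identical(r$steps, bfsStepsToSet(edge, targets))
  }
})

test_that("path priors respect inductive constraints and stay proper", {
  B <- array(0, c(4, 4, 2))
  B[2, 1, 1] <- 1  # path 1: 1 -> 2 (leads to reward)
  B[3, 1, 2] <- 1  # path 2: 1 -> 3 (precluded)
  B[4, 2, 1] <- 1  # 2 -> 4 (rewarded)
  reach <- inductiveReachability(B, rewardedSet = 4)
  pr <- planNextEvent(B, 1L, reach)
  expect_equal(sum(pr), 1)
  expect_gt(pr[1L], 0.999)  # single viable successor dominates
  # two viable successors with equal expected free energy share the prior
  B2 <- array(0, c(3, 3, 2))
  B2[2, 1, 1] <- 1; B2[3, 1, 2] <- 1
  r2 <- inductiveReachability(B2, rewardedSet = c(2, 3))
  pr2 <- planNextEvent(B2, 1L, r2)
  expect_equal(pr2, c(0.5, 0.5), tolerance = 1e-9)
  # constrained-softmax hand computation on a 4-state toy
  efe <- data.frame(G = c(0.5, 1.5))
  pr3 <- planNextEvent(B2, 1L, r2, Etop = c(2, 1), efe = efe)
  hand <- softmax(log(c(2, 1) / 3) - c(0.5, 1.5))
  expect_equal(pr3, hand, tolerance = 1e-9)
  # all successors precluded: uniform fallback with a warning
  B3 <- array(0, c(3, 3, 1)); B3[3, 1, 1] <- 1
  r3 <- list(steps = c(Inf, 0, Inf), rewarded = 2L)
  expect_warning(pr4 <- planNextEvent(B3, 1L, r3), "precluded")
  expect_equal(pr4, 1)
})

test_that("action selection realizes predictions, with a sticky hand when asked", {
  expect_error(selectAction(5, 5, candidates = integer(0)), "empty")
  # prediction left of the paddle: move left deterministically
  expect_equal(selectAction(4, 6, stickyP = 0)$action, -1L)
  expect_equal(selectAction(6, 6, stickyP = 0)$action, 0L)
  expect_equal(selectAction(9, 6, stickyP = 0)$action, 1L)
  # sticky hand with a symmetric posterior: empirical frequencies uniform
  set.seed(123)
  acts <- replicate(1000, selectAction(6, 2, stickyP = 1,
                                       precision = 0)$action)
  freq <- table(factor(acts, levels = c(-1, 0, 1))) / 1000
  # binomial 99.9% CI around 1/3 for n = 1000
  expect_true(all(abs(freq - 1 / 3) < 3.3 * sqrt(1 / 3 * 2 / 3 / 1000)))
})
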