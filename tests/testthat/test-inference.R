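test_that("posterior marginals match brute-force enumeration on toy chains", {
  set.seed(13)
  for (rep in 1:6) {
    S <- sample(2:4, 1); P <- sample(1:2, 1); K <- S + 1L; Tn <- 3L
    A <- normalizeCounts(matrix(rexp(K * S) + 0.05, K, S))
    B <- normalizeCounts(array(rexp(S * S * P) + 0.05, c(S, S, P)))
    Dt <- rexp(S) + 0.2; Et <- rexp(P) + 0.2
    m <- toyChainModel(A, B, Dtop = Dt, Etop = Et, floor = 0)
    o <- sample.int(K, Tn, replace = TRUE)
    post <- infer(m, toyObs(o, K))
    oracle <- enumerateChain(A, B, Dt, Et, o)
    expect_equal(post@s[[1L]][[1L]], oracle$s, tolerance = 1e-6)
    expect_equal(post@logZ, oracle$logZ, tolerance = 1e-6)
    expect_equal(unname(post@u[[1L]][[1L]][, 1:2, drop = FALSE]),
                 unname(oracle$u), tolerance = 1e-6)
  }
})

test_that("categorical posteriors are proper and simple cases are exact", {
  # precise one-hot likelihood pins the posterior
  A <- diag(3)
  B <- array(diag(3), c(3, 3, 1))
  m <- toyChainModel(A, B)
  post <- infer(m, toyObs(c(2L, 2L), 3))
  expect_equal(post@s[[1L]][[1L]][, 1L], c(0, 1, 0), tolerance = 1e-9)
  # two equally likely states under a uniform observation
  stream <- asStream(toyObs(c(1L, 1L), 3))
  stream$prob[[1L]][[1L]][] <- 1 / 3
  A2 <- matrix(c(1, 0, 0, 0, 1, 0), 3)  # two states, identity-ish columns
  m2 <- toyChainModel(A2, array(diag(2), c(2, 2, 1)))
  p2 <- infer(m2, stream)
  expect_equal(p2@s[[1L]][[1L]][, 1L], c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(abs(colSums(p2@s[[1L]][[1L]]) - 1) < 1e-9))
  expect_error(infer(m2, toyObs(c(1L, 1L), 5)), "alphabet")
})

test_that("ELBO equals -ln(N) for a model of N distinct exemplars", {
  g <- rgm:::demoGlyphModel(1, nClasses = 3, perClass = 4)
  m <- g$base
  countFloor(m) <- 0
  # one full training exemplar at a time: evidence 1/12 each
  stream <- asStream(g$obs)
  first <- list(prob = lapply(stream$prob, function(gs)
    lapply(gs, function(x) x[, 1L, drop = FALSE])),
    alphabet = stream$alphabet, R = 1L, breaks = 1L)
  post <- infer(m, first)
  expect_equal(post@logZ, -log(12), tolerance = 1e-6)
})

test_that("recognition inverts generation for every top state", {
  d <- rgm:::demoPeriodicModel(nFrames = 32L, period = 16L)
  S <- levelStates(d$model)[nLevels(d$model)]
  for (k in seq_len(S)) {
    gen <- generateFrom(d$model, topState = k, horizon = 1)
    post <- infer(d$model, gen$obs)
    expect_equal(topStates(post)[1L], k)
  }
})

test_that("generation cycles the learned orbit and is seed-reproducible", {
  d <- rgm:::demoPeriodicModel()
  cs <- compressSequence(d$model, d$obs)
  gen <- generateFrom(d$model, topState = cs$top[1L], horizon = 32)
  # 128 frames = 32 top events: the 8-event orbit cycles exactly 4 times
  expect_equal(dim(gen$frames)[4L], 128L)
  expect_equal(sum(gen$top == cs$top[1L]), 4L)
  expect_equal(gen$top, rep(cs$top[1:8], 4))
  # one top period reproduces the training cycle exactly
  gen1 <- generateFrom(d$model, topSeq = cs$top)
  for (g in seq_along(d$obs@idx))
    expect_identical(gen1$obs@idx[[g]], d$obs@idx[[g]])
  # sampled generation under a fixed seed is reproducible bit-exactly
  sA <- generateFrom(d$model, topState = 1, horizon = 8, mode = "sample", seed = 99)
  sB <- generateFrom(d$model, topState = 1, horizon = 8, mode = "sample", seed = 99)
  expect_identical(sA$obs@idx, sB$obs@idx)
  expect_error(generateFrom(d$model, topState = 1000), "invalid top state")
})

test_that("timescale separation: one level step spans R child steps", {
  obs <- randomSymbolObs(2, 3, 32, seed = 4)
  m <- fastStructureLearn(obs, list(list(R = 2L, merge = mergeAll(2L)),
                                    list(R = 2L, merge = mergeAll(1L))))
  post <- infer(m, obs)
  expect_equal(ncol(post@s[[1L]][[1L]]), 32L)
  expect_equal(ncol(post@s[[2L]][[1L]]), 16L)
  expect_equal(ncol(post@s[[3L]][[1L]]), 8L)
})

test_that("classification scores exemplars high and noise low", {
  g <- rgm:::demoGlyphModel(1, nClasses = 3, perClass = 4)
  cl <- classify(g$model, g$obs)
  expect_equal(cl$class, g$labels)
  expect_true(all(apply(cl$posterior, 2, max) > 0.99))
  expect_true(all(abs(colSums(cl$posterior) - 1) < 1e-9))
  # uniform-noise image scores far below the training exemplars
  set.seed(2)
  noise <- array(runif(32 * 32), c(32, 32, 1, 1))
  part <- g$partition
  nobs <- encodeFrames(noise, part, g$codecs)
  cn <- classify(g$model, nobs)
  expect_lt(cn$elbo[1L], min(cl$elbo) - 20)
  # Occam window flags it as unclassifiable
  thr <- min(cl$elbo) - 1
  expect_false(classify(g$model, nobs, occamThreshold = thr)$accepted[1L])
  expect_error(classify(g$base, g$obs), "label level")
})

test_that("free energy is non-increasing across fixed-point sweeps", {
  set.seed(31)
  for (rep in 1:8) {
    S <- sample(2:4, 1); R <- sample(2:4, 1); P <- sample(1:3, 1)
    L <- matrix(rnorm(S * R, sd = 2), S, R)
    lnB <- log(normalizeCounts(array(rexp(S * S * P) + 0.05, c(S, S, P))))
    r <- vmpFixedPoint(L, lnB, lnD = log(rep(1 / S, S)),
                       lnE = log(rep(1 / P, P)))
    expect_true(all(diff(r$F) <= 1e-9))
    expect_true(all(abs(colSums(r$qs) - 1) < 1e-9))
  }
  expect_error(vmpFixedPoint(matrix(NaN, 2, 2),
                             log(array(diag(2), c(2, 2, 1))),
                             log(c(.5, .5)), 0), "numerical guard")
})

test_that("pattern completion fills masked quadrants from the periodic video", {
  d <- rgm:::demoPeriodicModel()
  stream <- asStream(d$obs)
  stream <- maskStream(stream, 2:4)  # observe one quadrant only
  comp <- completeSequence(d$model, stream)
  for (g in 2:4) expect_identical(comp$obs@idx[[g]], d$obs@idx[[g]])
  # fully observed: completion agrees with the observation itself
  comp2 <- completeSequence(d$model, asStream(d$obs))
  for (g in 1:4) expect_identical(comp2$obs@idx[[g]], d$obs@idx[[g]])
  # all-missing stream returns the prior predictive without error
  blank <- maskStream(asStream(d$obs), 1:4)
  expect_s4_class(completeSequence(d$model, blank)$post, "Posterior")
})

test_that("ambiguous prefixes split posterior mass until disambiguated", {
  # two training sequences sharing their first symbol: A,B vs A,C
  obs <- toyObs(c(1L, 2L, 1L, 3L), 3, breaks = c(1L, 3L))
  m <- fastStructureLearn(obs, list(list(R = 2L, merge = mergeAll(1L))))
  expect_equal(levelStates(m)[2L], 2L)
  countFloor(m) <- 0
  # observe the shared prefix with the second step masked
  stream <- asStream(toyObs(c(1L, 2L), 3))
  stream$prob[[1L]][[1L]][, 2L] <- 1 / 3
  post <- infer(m, stream)
  expect_equal(post@s[[2L]][[1L]][, 1L], c(0.5, 0.5), tolerance = 1e-9)
  # disambiguating evidence resolves it
  post2 <- infer(m, toyObs(c(1L, 3L), 3))
  expect_equal(post2@s[[2L]][[1L]][2L, 1L], 1, tolerance = 1e-9)
})
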