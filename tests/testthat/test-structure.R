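test_that("unique state columns appear once, in order of first appearance", {
  m <- matrix(c(1, 2,  3, 1,  1, 2), 2)  # columns x, y, x
  u <- uniqueStateColumns(m, c(3, 3))
  expect_equal(ncol(u$states), 2L)
  expect_equal(u$seq, c(1L, 2L, 1L))
  expect_true(all(colSums(u$A[[1L]]) == 1))  # one-hot columns
  expect_error(uniqueStateColumns(matrix(integer(0), 1, 0)), "empty")
  # hashing oracle on random sequences
  set.seed(5)
  for (i in 1:10) {
    mm <- matrix(sample.int(3, 30, replace = TRUE), 3)
    u <- uniqueStateColumns(mm, c(3, 3, 3))
    expect_equal(ncol(u$states),
                 length(unique(apply(mm, 2, paste, collapse = "-"))))
  }
})

test_that("unique transitions allocate one path slice per distinct successor", {
  # deterministic cycle: single permutation slice
  tr <- uniqueTransitions(c(1, 2, 3, 1, 2, 3, 1), nStates = 3)
  expect_equal(tr$nPaths, 1L)
  expect_true(all(colSums(tr$B[, , 1]) == 1))
  expect_equal(which(tr$B[, 1, 1] == 1), 2L)
  # source 1 goes to 2 and to 3: two slices
  tr2 <- uniqueTransitions(c(1, 2, 1, 3), nStates = 3)
  expect_equal(tr2$nPaths, 2L)
  # enumeration of successor sets: slices needed = max out-degree
  set.seed(9)
  for (i in 1:10) {
    s <- sample.int(4, 40, replace = TRUE)
    tr <- uniqueTransitions(s, 4)
    outdeg <- vapply(1:4, function(a)
      length(unique(s[which(head(s, -1) == a) + 1L])), integer(1L))
    expect_equal(tr$nPaths, max(outdeg, 1L))
  }
  # transitions across breaks are not recorded
  tr3 <- uniqueTransitions(c(1, 2, 1, 2), nStates = 2, breaks = c(1L, 3L))
  expect_true(is.na(tr3$u[2L]))
})

test_that("coarse graining forms parent super-symbols that expand back exactly", {
  s <- list(c(1, 2, 1, 2, 3, 1), c(2, 2, 1, 1, 2, 2))
  u <- list(c(1, 1, 2), c(1, 2, 1))
  cg <- coarseGrain(s, u, R = 2, merge = list(c(1, 2)))
  expect_equal(length(cg$seq[[1L]]), 3L)
  # constant sequence gives one repeated super-symbol
  cg2 <- coarseGrain(list(rep(1L, 6)), list(rep(1L, 3)), 2, list(1L))
  expect_equal(cg2$nStates, 1L)
  expect_equal(cg2$seq[[1L]], rep(1L, 3))
  # expanding the super-symbols reproduces the original indices
  for (G in 1L) for (sg in seq_along(cg$seq[[G]])) {
    k <- cg$seq[[G]][sg]
    for (i in 1:2) {
      D <- cg$maps[[G]][[i]]$D; E <- cg$maps[[G]][[i]]$E
      expect_equal(which.max(D[, k]), s[[i]][(sg - 1) * 2 + 1])
      expect_equal(which.max(E[, k]), u[[i]][sg])
    }
  }
})

test_that("structure learning is deterministic and lossless on symbolic data", {
  obs <- randomSymbolObs(2, alphabet = 3, Tn = 32, seed = 21)
  sch <- list(list(R = 2L, merge = mergeAll(2L)),
              list(R = 2L, merge = mergeAll(1L)))
  m1 <- fastStructureLearn(obs, sch)
  m2 <- fastStructureLearn(obs, sch)
  expect_identical(m1@levels, m2@levels)
  # lossless generation from the inferred top trajectory (pre-floor counts)
  cs <- compressSequence(m1, obs)
  gen <- generateFrom(m1, topSeq = cs$top)
  for (g in 1:2) expect_identical(gen$obs@idx[[g]], obs@idx[[g]])
  # top-state bound: at most T / prod(R) states
  expect_lte(levelStates(m1)[nLevels(m1)], 32 / 4)
  # segment-hash oracle for the top-state count
  key <- vapply(seq_len(8), function(sg)
    paste(obs@idx[[1L]][, (sg - 1) * 4 + 1:4],
          obs@idx[[2L]][, (sg - 1) * 4 + 1:4], collapse = ","), character(1))
  expect_equal(levelStates(m1)[3L], length(unique(key)))
})

test_that("single repeated frame collapses to one state at every level", {
  idx <- list(matrix(2L, 1, 16), matrix(1L, 1, 16))
  obs <- new("DiscreteObservation", idx = idx, alphabet = list(3L, 3L),
             R = 1L, breaks = 1L)
  m <- fastStructureLearn(obs, list(list(R = 2L, merge = mergeAll(2L)),
                                    list(R = 2L, merge = mergeAll(1L))))
  expect_equal(unname(levelStates(m)), c(2L, 1L, 1L))
})

test_that("misaligned episode breaks and bad merges are rejected", {
  obs <- randomSymbolObs(2, 3, 16, seed = 1, breaks = c(1L, 4L))
  sch <- list(list(R = 2L, merge = mergeAll(2L)))
  expect_error(fastStructureLearn(obs, sch), "aligned")
  obs2 <- randomSymbolObs(2, 3, 16, seed = 1)
  expect_error(fastStructureLearn(obs2, list(list(R = 2L, merge = list(1L)))),
               "partition")
  # trailing steps that do not fill a segment are dropped with a warning
  obs3 <- randomSymbolObs(1, 3, 15, seed = 2)
  expect_warning(m3 <- fastStructureLearn(obs3, list(list(R = 2L, merge = mergeAll(1L)))),
                 "trailing")
})

test_that("label levels map classes onto their exemplars exhaustively", {
  g <- rgm:::demoGlyphModel(1, nClasses = 3, perClass = 4)
  expect_true(g$model@labelLevel)
  top <- g$model@levels[[length(g$model@levels)]]
  expect_equal(top@nStates[1L], 3L)
  D <- top@A[[1L]][[1L]]$D
  expect_equal(dim(D), c(12L, 3L))
  expect_equal(unname(colSums(D)), rep(4, 3))
  # every exemplar reachable from exactly one class
  expect_true(all(rowSums(D > 0) == 1))
  # class-conditional generation yields only that class's exemplars
  cl <- classify(g$model, g$obs)
  for (k in 1:3) {
    exemplars <- which(D[, k] > 0)
    for (e in exemplars) {
      gen <- generateFrom(g$base, topState = e, horizon = 1)
      p <- classify(g$model, gen$obs)
      expect_equal(p$class[1L], k)
    }
  }
  expect_error(addLabelLevel(g$model, 1:12), "label level")
  expect_error(addLabelLevel(g$base, 1:5, obs = g$obs), "match")
  # single class: top level is a single state
  m1 <- addLabelLevel(g$base, rep(1L, 12), obs = g$obs)
  expect_equal(m1@levels[[length(m1@levels)]]@nStates[1L], 1L)
})

test_that("growth gating accepts novel causes and rejects duplicates", {
  a <- diag(4) * 8
  dup <- gateGrowth(a, c(1, 0, 0, 0))
  expect_false(dup$accepted)
  orth <- gateGrowth(rbind(diag(3) * 8, 0), c(0, 0, 0, 1))
  expect_true(orth$accepted)
  # 2-state toy: decision matches direct evaluation of both terms
  a2 <- matrix(c(8, 0, 0, 8), 2)
  o <- c(1, 0)
  g <- gateGrowth(a2, o, floor = 1 / 32)
  ev <- function(af) {
    p <- normalizeCounts(af)
    max(log(1 / ncol(af)) + log(colSums(p * o)))
  }
  f <- 1 / 32
  dF <- ev(cbind(a2 + f, o + f)) - ev(a2 + f)
  dG <- bruteMI(cbind(a2 + f, o + f)) - bruteMI(a2 + f)
  expect_equal(g$deltaF, dF, tolerance = 1e-10)
  expect_equal(g$deltaG, dG, tolerance = 1e-10)
  expect_equal(g$accepted, (dF + dG) > 0)
})
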