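test_that("block partitions tile exactly and reject non-divisible inputs", {
  f32 <- array(runif(32 * 32 * 4), c(32, 32, 1, 4))
  expect_equal(nGroups(fitPartition(f32, c(8, 8))), 16L)
  f128 <- array(0, c(128, 128, 1, 2))
  expect_equal(nGroups(fitPartition(f128, c(32, 32))), 16L)
  f4 <- array(0, c(4, 4, 1, 1))
  expect_equal(nGroups(fitPartition(f4, c(4, 4))), 1L)
  expect_error(fitPartition(f32, c(5, 5)), "divisible")
  expect_error(fitPartition(f32, c(8, 8), R = 3), "divisible")
  # every pixel in exactly one block
  p <- fitPartition(f32, c(8, 8))
  seen <- matrix(0L, 32, 32)
  for (g in seq_len(nGroups(p))) {
    px <- rgm:::groupPixels(p, g)
    seen[px$rows, px$cols] <- seen[px$rows, px$cols] + 1L
  }
  expect_true(all(seen == 1L))
})

test_that("codecs retain energy-ranked components and quantize reversibly", {
  set.seed(7)
  x <- matrix(rnorm(64 * 40), 64, 40)
  cd <- fitCodec(x, maxVectors = 16, nLevels = 7)
  expect_lte(ncol(cd@basis), 16L)
  expect_true(cd@nLevels %% 2L == 1L)
  # retained subspace energy equals the sum of retained squared singular values
  xc <- x - rowMeans(x)
  energy <- sum(crossprod(cd@basis, xc)^2)
  expect_equal(energy, sum(cd@singularValues^2), tolerance = 1e-8)
  # constant group: zero components
  cd0 <- fitCodec(matrix(3, 10, 5), maxVectors = 4, nLevels = 5)
  expect_equal(ncol(cd0@basis), 0L)
  expect_error(fitCodec(matrix(0, 4, 0)), "empty")
})

test_that("SVD bases beat random orthonormal bases of the same rank", {
  set.seed(11)
  base <- matrix(rnorm(32 * 3), 32, 3) %*% matrix(rnorm(3 * 50), 3, 50)
  x <- base + 0.05 * matrix(rnorm(32 * 50), 32, 50)
  xc <- x - rowMeans(x)
  cd <- fitCodec(x, maxVectors = 3, nLevels = 7, retention = 0)
  k <- ncol(cd@basis)
  errSvd <- sum((xc - cd@basis %*% crossprod(cd@basis, xc))^2)
  for (i in 1:100) {
    q <- qr.Q(qr(matrix(rnorm(32 * k), 32, k)))
    errRnd <- sum((xc - q %*% crossprod(q, xc))^2)
    expect_gte(errRnd, errSvd - 1e-8)
  }
})

test_that("encode/decode round trip obeys the half-bin error bound", {
  fr <- periodicVideo(16L, 8L, imageSize = 16L)
  part <- fitPartition(fr, c(8, 8), R = 2)
  cds <- lapply(seq_len(nGroups(part)), function(g)
    fitCodec(rgm:::blockMatrix(fr, part, g), maxVectors = 16, nLevels = 7,
             retention = 0))
  obs <- encodeFrames(fr, part, cds)
  # determinism
  obs2 <- encodeFrames(fr, part, cds)
  expect_identical(obs@idx, obs2@idx)
  # alphabet bound
  lev <- uniqueStateColumns(obs@idx[[1L]], obs@alphabet[[1L]])
  expect_lte(ncol(lev$states), 7^length(obs@alphabet[[1L]]))
  dec <- decodeFrames(obs, part, cds)
  for (g in seq_len(nGroups(part))) {
    px <- rgm:::groupPixels(part, g)
    err <- max(abs(dec[px$rows, px$cols, , ] - fr[px$rows, px$cols, , ]))
    expect_lte(err, rgm:::codecErrorBound(cds[[g]]) + 1e-10)
  }
  expect_error(encodeFrames(fr[1:8, 1:8, , , drop = FALSE], part, cds), "shape")
})

test_that("all-zero frames map to the central quantization level", {
  set.seed(3)
  fr <- array(rnorm(16 * 16 * 8), c(16, 16, 1, 8))
  fr <- sweep(fr, c(1, 2, 3), apply(fr, c(1, 2, 3), mean))  # zero-mean pixels
  part <- fitPartition(fr, c(8, 8), R = 1)
  cds <- lapply(seq_len(nGroups(part)), function(g) {
    cd <- fitCodec(rgm:::blockMatrix(fr, part, g), maxVectors = 4, nLevels = 5)
    cd@mean[] <- 0  # zero-mean codec by construction
    cd
  })
  z <- array(0, c(16, 16, 1, 1))
  obs <- encodeFrames(z, part, cds)
  for (g in seq_along(obs@idx))
    expect_true(all(obs@idx[[g]] == (cds[[g]]@nLevels + 1L) %/% 2L))
})

test_that("the time-frequency frontend localizes tones and inverts", {
  sr <- 8000
  tt <- (0:7999) / sr
  wav <- sin(2 * pi * 440 * tt)
  tf <- audioToTF(wav, sr, fMin = 40, fMax = 3000, nBins = 48)
  peak <- tf$freqs[which.max(rowSums(tf$mag))]
  others <- tf$freqs[order(abs(tf$freqs - 440))][1L]
  expect_equal(peak, others)   # energy maximal in the bin nearest 440 Hz
  # silence
  expect_equal(max(audioToTF(rep(0, 2000), sr, 40, 3000, nBins = 16)$mag), 0)
  # inverse: re-analysis correlates > 0.9 on band-limited tones
  wav2 <- sin(2 * pi * 440 * tt) + 0.5 * sin(2 * pi * 1100 * tt)
  tf2 <- audioToTF(wav2, sr, 40, 3000, nBins = 48)
  rec <- tfToAudio(tf2)
  tf3 <- audioToTF(rec, sr, 40, 3000, nBins = 48)
  expect_gt(cor(as.vector(tf2$mag), as.vector(tf3$mag)), 0.9)
  expect_error(audioToTF(wav, sr, 40, 6000, 16), "Nyquist")
})

test_that("distinct chirp events occupy distinct dominant bins", {
  sr <- 8000
  a <- toneSequence(rbind(c(300, 400, 0.3)), sr)
  b <- toneSequence(rbind(c(1500, 2000, 0.3)), sr)
  tfa <- audioToTF(a, sr, 100, 3000, nBins = 32)
  tfb <- audioToTF(b, sr, 100, 3000, nBins = 32)
  expect_true(which.max(rowSums(tfa$mag)) != which.max(rowSums(tfb$mag)))
})
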