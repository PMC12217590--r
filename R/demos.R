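# End-to-end demonstration pipelines over the synthetic worlds. Each demo
# returns a machine-readable report list; all randomness flows through the
# seed argument.

#' Build the glyph-classification worked example
#'
#' Generates distinct glyph exemplars (13 per class by default), quantizes
#' them with the demo codec (8x8 pixel blocks, 7 levels, at most 16 singular
#' vectors), runs fast structure learning to a single image-spanning factor,
#' and adds a class-label level.
#'
#' @param seed integer seed for the glyph generator.
#' @param nClasses,perClass class and exemplar-per-class counts.
#' @return list with \code{model} (label-level RGModel), \code{base} (the
#'   unsupervised model), \code{obs}, \code{labels}, \code{frames},
#'   \code{partition}, \code{codecs}.
#' @export
demoGlyphModel <- function(seed = 1L, nClasses = 10L, perClass = 13L) {
  gl <- glyphImages(nClasses, perClass, imageSize = 32L, seed = seed)
  n <- dim(gl$frames)[4L]
  part <- fitPartition(gl$frames, c(8L, 8L), R = 1L)
  cds <- lapply(seq_len(nGroups(part)), function(g)
    fitCodec(blockMatrix(gl$frames, part, g), maxVectors = 16L, nLevels = 7L))
  obs <- encodeFrames(gl$frames, part, cds, breaks = seq_len(n))
  schedule <- list(list(R = 1L, merge = gridMerge2x2(4L, 4L)),
                   list(R = 1L, merge = mergeAll(4L)))
  m <- fastStructureLearn(obs, schedule, partition = part, codecs = cds)
  ml <- addLabelLevel(m, gl$labels, obs = obs)
  list(model = ml, base = m, obs = obs, labels = gl$labels, frames = gl$frames,
       partition = part, codecs = cds)
}

#' Build the periodic-video worked example
#'
#' Encodes a periodic articulated-shape video with a two-frame voxel codec
#' and one pairwise temporal ascent: each top-level event spans four frames.
#'
#' @param nFrames,period video length and cycle length in frames.
#' @return list with \code{model}, \code{obs}, \code{frames},
#'   \code{partition}, \code{codecs}.
#' @export
demoPeriodicModel <- function(nFrames = 64L, period = 32L) {
  fr <- periodicVideo(nFrames, period, imageSize = 32L)
  part <- fitPartition(fr, c(16L, 16L), R = 2L)
  cds <- lapply(seq_len(nGroups(part)), function(g)
    fitCodec(blockMatrix(fr, part, g), maxVectors = 16L, nLevels = 7L))
  obs <- encodeFrames(fr, part, cds)
  schedule <- list(list(R = 2L, merge = mergeAll(4L)))
  m <- fastStructureLearn(obs, schedule, partition = part, codecs = cds)
  list(model = m, obs = obs, frames = fr, partition = part, codecs = cds)
}

#' Build the chaotic-video worked example
#'
#' Renders a Lorenz-driven ball video and renormalizes it with an eight-fold
#' total temporal coarse-graining (pairwise at the codec and at each of two
#' ascents), giving a three-level model whose top events span eight frames.
#'
#' @param seed integer seed for the stochastic integration.
#' @param nFrames frames to simulate.
#' @return list with \code{model}, \code{obs}, \code{lorenz},
#'   \code{partition}, \code{codecs}.
#' @export
demoLorenzModel <- function(seed = 1L, nFrames = 512L) {
  lz <- lorenzVideo(nFrames, dt = 0.02, noiseSd = 2, imageSize = 32L,
                    seed = seed)
  part <- fitPartition(lz$frames, c(8L, 8L), R = 2L)
  cds <- lapply(seq_len(nGroups(part)), function(g)
    fitCodec(blockMatrix(lz$frames, part, g), maxVectors = 16L, nLevels = 5L))
  obs <- encodeFrames(lz$frames, part, cds)
  schedule <- list(list(R = 2L, merge = gridMerge2x2(4L, 4L)),
                   list(R = 2L, merge = mergeAll(4L)))
  m <- fastStructureLearn(obs, schedule, partition = part, codecs = cds)
  list(model = m, obs = obs, lorenz = lz, partition = part, codecs = cds)
}

#' Build a grid-game event model from random play
#'
#' Generates random play, selects reward-bracketed miss-free segments,
#' renormalizes the selected frames with two pairwise temporal
#' coarse-grainings (events span four frames), and assembles the playing
#' agent.
#'
#' @param seed integer seed.
#' @param budget training frames after selection.
#' @param randomFrames size of the random-play pool.
#' @param env "pong" or "breakout".
#' @param persistence serial correlation of the random actions (0 = i.i.d.).
#' @return list with \code{model}, \code{agent}, \code{train}, \code{log}.
#' @export
demoPongModel <- function(seed = 1L, budget = 1024L, randomFrames = 21280L,
                          env = "pong", persistence = 0) {
  log <- randomPlay(env, randomFrames, seed = seed, persistence = persistence)
  log <- selectSegments(log)
  train <- trainingObservation(log, budget = budget, align = 4L)
  schedule <- list(list(R = 2L, merge = mergeAll(length(train$obs@idx))),
                   list(R = 2L, merge = mergeAll(1L)))
  m <- fastStructureLearn(train$obs, schedule, floor = 1 / 128)
  agent <- makeAgent(m, train)
  list(model = m, agent = agent, train = train, log = log)
}

#' Run an end-to-end demonstration
#'
#' Executes one of the worked examples on its synthetic fixture and returns
#' a machine-readable report: per-level state counts, the quantities the
#' example is about (classification accuracy, event counts, generation
#' round trips, play statistics), and the seed used.
#'
#' @param name one of "digits", "dove", "lorenz", "birdsong", "pong",
#'   "breakout".
#' @param seed integer seed.
#' @param nSteps play length for the game demos.
#' @param stickyP shaky-hand probability for the game demos.
#' @return report list.
#' @export
runDemo <- function(name = c("digits", "dove", "lorenz", "birdsong", "pong",
                             "breakout"),
                    seed = 1L, nSteps = 512L, stickyP = 0) {
  name <- match.arg(name)
  rep0 <- list(demo = name, seed = seed)
  if (name == "digits") {
    d <- demoGlyphModel(seed)
    cl <- classify(d$model, d$obs)
    acc <- mean(cl$class == as.integer(factor(d$labels)))
    rep0$levelStates <- as.integer(levelStates(d$model))
    rep0$exemplarStates <- levelStates(d$base)[nLevels(d$base)]
    rep0$accuracy <- acc
    rep0$medianElbo <- stats::median(cl$elbo)
    rep0$posterior <- cl$posterior
    rep0$model <- d$model
  } else if (name == "dove") {
    d <- demoPeriodicModel()
    cs <- compressSequence(d$model, d$obs)
    gen <- generateFrom(d$model, topState = cs$top[1L],
                        horizon = 2L * length(cs$top))
    rep0$levelStates <- as.integer(levelStates(d$model))
    rep0$topEvents <- length(unique(cs$top))
    rep0$cycles <- sum(gen$top == cs$top[1L])
    rep0$lossless <- identical(gen$obs@idx[[1L]][, seq_len(ncol(d$obs@idx[[1L]]))],
                               d$obs@idx[[1L]])
    rep0$model <- d$model
  } else if (name == "lorenz") {
    d <- demoLorenzModel(seed)
    cs <- compressSequence(d$model, d$obs)
    rep0$levelStates <- as.integer(levelStates(d$model))
    rep0$topEvents <- length(unique(cs$top))
    rep0$model <- d$model
  } else if (name == "birdsong") {
    d <- demoBirdsongModel(seed)
    rep0$levelStates <- as.integer(levelStates(d$model))
    rep0$topEvents <- d$topEvents
    rep0$tfCorrelation <- d$tfCorrelation
    rep0$model <- d$model
  } else {
    env <- name
    budget <- if (env == "pong") 1024L else 2048L
    d <- demoPongModel(seed, budget = budget, randomFrames = 60000L,
                       env = env, persistence = 0.7)
    play <- playEpisode(d$agent, nSteps = nSteps, stickyP = stickyP,
                        seed = seed, learn = TRUE)
    rep0$levelStates <- as.integer(levelStates(d$model))
    rep0$topEvents <- levelStates(d$model)[nLevels(d$model)]
    rep0$trainingFrames <- ncol(d$train$obs@idx[[1L]])
    rep0$hits <- sum(play$rewards)
    rep0$misses <- sum(play$misses)
    rep0$meanElboFirstHalf <- mean(play$elbo[seq_len(length(play$elbo) %/% 2)])
    rep0$meanElboSecondHalf <- mean(play$elbo[-seq_len(length(play$elbo) %/% 2)])
    rep0$model <- play$model
    rep0$agent <- d$agent
  }
  rep0
}

#' Build the birdsong worked example
#'
#' Synthesizes stereotyped chirp calls, maps them through the Morlet
#' time-frequency frontend, and renormalizes the time-frequency image into
#' a sequence of call events.
#'
#' @param seed integer seed (kept for interface symmetry; the call script is
#'   deterministic).
#' @return list with \code{model}, \code{obs}, \code{tf},
#'   \code{topEvents}, \code{tfCorrelation}.
#' @export
demoBirdsongModel <- function(seed = 1L) {
  # two stereotyped calls, each a crescendo of chirps, over a quiet rumble
  sr <- 8820
  ev <- rbind(c(1200, 2400, 0.12), c(1500, 3000, 0.12), c(1800, 3600, 0.12),
              c(900, 1800, 0.12), c(1100, 2200, 0.12), c(1400, 2800, 0.12),
              c(1700, 3400, 0.12), c(2000, 3900, 0.12))
  wav <- toneSequence(ev, sr)
  tf <- audioToTF(wav, sr, fMin = 40, fMax = 4000, nBins = 64,
                  envelopeMs = 32, hopMs = 8)
  nT <- (ncol(tf$mag) %/% 16L) * 16L
  img <- array(tf$mag[, seq_len(nT)], c(64L, 1L, 1L, nT))
  part <- fitPartition(img, c(4L, 1L), R = 2L)
  cds <- lapply(seq_len(nGroups(part)), function(g)
    fitCodec(blockMatrix(img, part, g), maxVectors = 16L, nLevels = 5L))
  obs <- encodeFrames(img, part, cds)
  schedule <- list(list(R = 2L, merge = mergeAll(16L)),
                   list(R = 2L, merge = mergeAll(1L)))
  m <- fastStructureLearn(obs, schedule, partition = part, codecs = cds)
  cs <- compressSequence(m, obs)
  dec <- decodeFrames(obs, part, cds)
  rec <- as.vector(dec)
  orig <- as.vector(img)
  list(model = m, obs = obs, tf = tf, topEvents = length(unique(cs$top)),
       tfCorrelation = stats::cor(rec, orig))
}
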