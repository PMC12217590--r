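# Synthetic environments and fixture generators: grid-world Pong/Breakout
# with sparse rewards, a Lorenz-SDE-driven ball video, a periodic
# articulated-shape video, distinct glyph exemplars, and chirp tones. All
# generators are deterministic under a seed.

GRID_W <- 12L
GRID_H <- 9L
# cell states: 1 background, 2 ball, 3/4/5 paddle left/mid/right, 6 target
CELL_BG <- 1L; CELL_BALL <- 2L; CELL_PL <- 3L; CELL_PM <- 4L; CELL_PR <- 5L
CELL_TARGET <- 6L

# small deterministic LCG kept inside the engine state, so stepping is a pure
# function of (state, action)
lcgNext <- function(x) (1103515245 * x + 12345) %% 2147483648
lcgUnif <- function(x) x / 2147483648

#' Initialize a Pong game state
#'
#' A 12 x 9 grid: the ball bounces with constant momentum inside the box; the
#' paddle (three contiguous cells on the bottom row) moves by one column per
#' step or stays. A hit (reward) reflects the ball; a miss re-serves it from
#' a fixed height at a seeded horizontal location around the centre.
#'
#' @param seed integer seed for the engine's internal generator.
#' @return engine state (list).
#' @export
pongInit <- function(seed = 1L) {
  list(game = "pong", ballX = 6L, ballY = 2L, vx = 1L, vy = 1L,
       paddle = 6L, reward = FALSE, miss = FALSE,
       rng = (abs(as.integer(seed)) + 7L) %% 2147483648,
       targets = integer(0))
}

#' Initialize a Breakout game state
#'
#' Adds three full rows of targets at the top; hitting the lowest remaining
#' row removes it (reward); hitting the last (golden) row resets the game.
#'
#' @param seed integer seed.
#' @return engine state (list).
#' @export
breakoutInit <- function(seed = 1L) {
  st <- pongInit(seed)
  st$game <- "breakout"
  st$targets <- c(1L, 1L, 1L)  # rows 1..3 present flags
  st$ballY <- 5L
  st
}

serveBall <- function(st) {
  st$rng <- lcgNext(st$rng)
  off <- as.integer(floor(lcgUnif(st$rng) * 5)) - 2L
  st$rng <- lcgNext(st$rng)
  st$ballX <- max(1L, min(GRID_W, 6L + off))
  st$ballY <- if (st$game == "breakout") 5L else 2L
  st$vx <- if (lcgUnif(st$rng) < 0.5) -1L else 1L
  st$vy <- 1L
  st
}

stepBall <- function(st) {
  nx <- st$ballX + st$vx
  ny <- st$ballY + st$vy
  if (nx < 1L) { nx <- 2L - nx; st$vx <- -st$vx }
  if (nx > GRID_W) { nx <- 2L * GRID_W - nx; st$vx <- -st$vx }
  ceiling <- 1L
  if (st$game == "breakout") {
    remaining <- which(st$targets == 1L)
    if (length(remaining)) {
      low <- max(remaining)  # lowest remaining target row
      if (ny <= low) {       # ball reaches the target band
        st$targets[low] <- 0L
        st$reward <- TRUE
        if (low == 1L) {     # golden row: reset the game
          st$targets <- c(1L, 1L, 1L)
          st$paddle <- 6L
          st <- serveBall(st)
          return(st)
        }
        ny <- low + 1L + (low + 1L - ny)
        if (ny == low + 1L) ny <- low + 2L
        st$vy <- 1L
        st$ballX <- nx; st$ballY <- min(ny, GRID_H - 1L)
        return(st)
      }
      ceiling <- low + 1L
    }
  }
  if (ny < ceiling) { ny <- 2L * ceiling - ny; st$vy <- -st$vy }
  if (ny > GRID_H - 1L) {
    if (abs(nx - st$paddle) <= 1L) {  # hit
      st$reward <- TRUE
      st$vy <- -st$vy
      ny <- 2L * (GRID_H - 1L) - ny
    } else {                          # miss: re-serve the ball
      st$miss <- TRUE
      if (st$game == "breakout") st$paddle <- 6L  # breakout resets the paddle
      st <- serveBall(st)
      return(st)
    }
  }
  st$ballX <- nx; st$ballY <- ny
  st
}

#' Advance a grid game by one step
#'
#' @param st engine state from \code{\link{pongInit}} or
#'   \code{\link{breakoutInit}}.
#' @param action -1 (left), 0 (stay), or 1 (right).
#' @return updated state; \code{st$reward}/\code{st$miss} flag the event that
#'   occurred during this step.
#' @export
gameStep <- function(st, action) {
  stopifnot(action %in% c(-1L, 0L, 1L))
  st$reward <- FALSE; st$miss <- FALSE
  st$paddle <- max(2L, min(GRID_W - 1L, st$paddle + as.integer(action)))
  stepBall(st)
}

#' Render a game state as a cell-state grid
#' @param st engine state.
#' @return integer matrix (9 x 12) over the cell alphabet.
#' @export
renderGrid <- function(st) {
  g <- matrix(CELL_BG, GRID_H, GRID_W)
  if (st$game == "breakout")
    for (r in which(st$targets == 1L)) g[r, ] <- CELL_TARGET
  g[GRID_H, st$paddle - 1L] <- CELL_PL
  g[GRID_H, st$paddle] <- CELL_PM
  g[GRID_H, st$paddle + 1L] <- CELL_PR
  g[st$ballY, st$ballX] <- CELL_BALL
  g
}

#' Render cell grids as TrueColor frames
#'
#' Expands each cell to a square tile of pixels with one fixed colour per
#' cell state (the pixel-space view of the game).
#'
#' @param grids list of cell matrices.
#' @param tile tile edge in pixels (default 32).
#' @return array (H*tile x W*tile x 3 x T).
#' @export
renderFrames <- function(grids, tile = 32L) {
  pal <- rbind(c(0, 0, 0), c(1, 1, 1), c(0.8, 0.2, 0.2), c(0.9, 0.3, 0.3),
               c(0.8, 0.2, 0.2), c(0.9, 0.8, 0.2))
  H <- nrow(grids[[1L]]); W <- ncol(grids[[1L]])
  out <- array(0, c(H * tile, W * tile, 3L, length(grids)))
  for (t in seq_along(grids)) for (ch in 1:3) {
    big <- pal[grids[[t]], ch]
    dim(big) <- c(H, W)
    out[, , ch, t] <- big[rep(seq_len(H), each = tile), rep(seq_len(W), each = tile)]
  }
  out
}

#' Random play in a grid game
#'
#' Uniform random actions; records frames (cell grids), full engine states,
#' actions, rewards and misses.
#'
#' @param env "pong" or "breakout".
#' @param nFrames number of steps.
#' @param seed seed for both the action stream and the engine.
#' @param persistence probability of repeating the previous action instead
#'   of redrawing uniformly (serially correlated random play; 0 gives
#'   i.i.d. uniform actions).
#' @return an \linkS4class{EpisodeLog}.
#' @export
randomPlay <- function(env = c("pong", "breakout"), nFrames, seed = 1L,
                       persistence = 0) {
  env <- match.arg(env)
  if (nFrames < 1L) stop("nFrames must be >= 1")
  set.seed(seed)
  st <- if (env == "pong") pongInit(seed) else breakoutInit(seed)
  frames <- vector("list", nFrames)
  states <- vector("list", nFrames)
  actions <- integer(nFrames)
  rewards <- logical(nFrames)
  misses <- logical(nFrames)
  acts <- sample(c(-1L, 0L, 1L), nFrames, replace = TRUE)
  if (persistence > 0 && nFrames > 1L) {
    keep <- stats::runif(nFrames) < persistence
    for (t in 2L:nFrames) if (keep[t]) acts[t] <- acts[t - 1L]
  }
  for (t in seq_len(nFrames)) {
    states[[t]] <- st
    st <- gameStep(st, acts[t])
    frames[[t]] <- renderGrid(st)
    actions[t] <- acts[t]
    rewards[t] <- st$reward
    misses[t] <- st$miss
  }
  new("EpisodeLog", frames = frames, states = states, actions = actions,
      rewards = rewards, misses = misses,
      segments = data.frame(from = integer(0), to = integer(0),
                            chain = integer(0)))
}

#' Select reward-bracketed training segments
#'
#' Keeps stretches that start at a previously rewarded outcome, end in the
#' subsequent hit, and contain no misses. Consecutive valid segments form
#' contiguous chains; each chain is trimmed to a multiple of \code{align}
#' frames and chains are accumulated until \code{budget} frames are reached.
#'
#' @param log an EpisodeLog from \code{\link{randomPlay}}.
#' @return the log with \code{segments} filled; use
#'   \code{\link{trainingObservation}} to extract the training set.
#' @export
selectSegments <- function(log) {
  rw <- which(log@rewards)
  if (length(rw) < 2L) stop("no rewarded segment found; generate more frames")
  seg <- data.frame(from = integer(0), to = integer(0), chain = integer(0))
  chain <- 0L
  lastTo <- -1L
  for (i in seq_len(length(rw) - 1L)) {
    a <- rw[i]; b <- rw[i + 1L]
    if (any(log@misses[(a + 1L):b])) next
    if (a != lastTo) chain <- chain + 1L
    seg <- rbind(seg, data.frame(from = a, to = b, chain = chain))
    lastTo <- b
  }
  if (nrow(seg) == 0L) stop("no rewarded segment found; generate more frames")
  log@segments <- seg
  log
}

#' Extract the training observation from selected segments
#'
#' Concatenates the selected chains (trimmed to the alignment) up to the
#' budget; episode breaks separate non-contiguous chains so that no
#' concatenation artifact is ever recorded as a transition.
#'
#' @param log an EpisodeLog after \code{\link{selectSegments}}.
#' @param budget total training frames wanted.
#' @param align chain length granularity (the model's frame span per event).
#' @param novel order chains by novelty first: chains contributing
#'   action-independent content (ball trajectories) not yet covered are
#'   ingested before repeats (active data selection); the remaining budget is
#'   filled chronologically.
#' @return list with \code{obs} (DiscreteObservation over the 108 cells),
#'   \code{frames} (list of grids), \code{rewards}, \code{starts} (engine
#'   state at each chain start), \code{times} (source frame index per
#'   training frame).
#' @export
trainingObservation <- function(log, budget = 1024L, align = 4L,
                                novel = TRUE) {
  seg <- log@segments
  chainIds <- unique(seg$chain)
  if (novel) {
    covered <- character(0)
    novelFirst <- integer(0); rest <- integer(0)
    for (ch in chainIds) {
      rows <- seg[seg$chain == ch, ]
      ts <- rows$from[1L]:rows$to[nrow(rows)]
      n <- (length(ts) %/% align) * align
      if (n == 0L) next
      ts <- ts[(length(ts) - n + 1L):length(ts)]
      ks <- vapply(seq_len(n %/% align), function(w)
        ballKeyOf(log@frames[ts[(w - 1L) * align + seq_len(align)]]),
        character(1L))
      if (any(!(ks %in% covered))) {
        novelFirst <- c(novelFirst, ch)
        covered <- union(covered, ks)
      } else rest <- c(rest, ch)
    }
    chainIds <- c(novelFirst, rest)
  }
  times <- integer(0)
  breaks <- integer(0)
  starts <- list()
  for (ch in chainIds) {
    rows <- seg[seg$chain == ch, ]
    ts <- rows$from[1L]:rows$to[nrow(rows)]
    n <- (length(ts) %/% align) * align
    if (n == 0L) next
    ts <- ts[(length(ts) - n + 1L):length(ts)]  # keep the chain-final hit
    room <- budget - length(times)
    if (room <= 0L) break
    if (length(ts) > room) {
      k <- (room %/% align) * align
      if (k == 0L) break
      ts <- ts[(length(ts) - k + 1L):length(ts)]
    }
    breaks <- c(breaks, length(times) + 1L)
    starts[[length(starts) + 1L]] <- log@states[[ts[1L]]]
    times <- c(times, ts)
  }
  if (length(times) == 0L) stop("no rewarded segment found; generate more frames")
  grids <- log@frames[times]
  list(obs = gridObservation(grids, breaks = breaks), frames = grids,
       rewards = log@rewards[times], starts = starts, times = times)
}

#' Cell grids as a discrete observation
#'
#' One group per cell (row-major), one variate per group over the cell-state
#' alphabet: the direct symbolic observation path that bypasses the SVD
#' frontend.
#'
#' @param grids list of integer cell matrices.
#' @param breaks episode starts.
#' @param alphabet alphabet size (default: max observed cell state).
#' @export
gridObservation <- function(grids, breaks = 1L, alphabet = NULL) {
  H <- nrow(grids[[1L]]); W <- ncol(grids[[1L]])
  Tn <- length(grids)
  if (is.null(alphabet)) alphabet <- max(vapply(grids, max, integer(1L)))
  idx <- vector("list", H * W)
  flat <- matrix(unlist(grids), H * W, Tn)  # cells row-major within column
  g <- 0L
  for (r in seq_len(H)) for (co in seq_len(W)) {
    g <- g + 1L
    idx[[g]] <- matrix(flat[(co - 1L) * H + r, ], 1L, Tn)
  }
  new("DiscreteObservation", idx = idx,
      alphabet = rep(list(as.integer(alphabet)), H * W),
      R = 1L, breaks = as.integer(breaks))
}

#' Lorenz-SDE-driven ball video
#'
#' Integrates the Lorenz system (sigma = 10, rho = 28, beta = 8/3) with
#' Euler-Maruyama state noise and renders a white disc whose position is the
#' scaled (x, y) pair of the first two hidden states, over a faint static
#' dotted-trajectory background.
#'
#' @param nFrames frames to render.
#' @param dt integration step per frame (split into \code{substeps}).
#' @param noiseSd state-noise standard deviation (per unit time).
#' @param imageSize frame edge in pixels.
#' @param seed integer seed.
#' @param substeps Euler-Maruyama substeps per frame.
#' @return list with \code{frames} (imageSize x imageSize x 1 x nFrames),
#'   \code{states} (3 x nFrames matrix).
#' @export
lorenzVideo <- function(nFrames, dt = 0.02, noiseSd = 2, imageSize = 32L,
                        seed = 1L, substeps = 4L) {
  if (dt <= 0) stop("dt must be positive")
  set.seed(seed)
  sg <- 10; rh <- 28; bt <- 8 / 3
  x <- c(1, 1, 20)
  h <- dt / substeps
  states <- matrix(0, 3L, nFrames)
  for (t in seq_len(nFrames)) {
    for (k in seq_len(substeps)) {
      dx <- c(sg * (x[2] - x[1]),
              x[1] * (rh - x[3]) - x[2],
              x[1] * x[2] - bt * x[3])
      x <- x + h * dx + noiseSd * sqrt(h) * rnorm(3)
    }
    states[, t] <- x
  }
  # affine map: attractor wings fill ~80% of the frame
  sx <- (states[1L, ] + 20) / 40
  sy <- (states[2L, ] + 27) / 54
  px <- round(0.1 * imageSize + sx * 0.8 * (imageSize - 1L))
  py <- round(0.1 * imageSize + sy * 0.8 * (imageSize - 1L))
  px <- pmin(pmax(px, 1), imageSize); py <- pmin(pmax(py, 1), imageSize)
  bg <- matrix(0, imageSize, imageSize)
  bg[cbind(py, px)] <- 0.25  # dotted trajectory backdrop
  frames <- array(0, c(imageSize, imageSize, 1L, nFrames))
  rad <- max(1L, round(imageSize / 16))
  for (t in seq_len(nFrames)) {
    f <- bg
    rr <- max(1L, py[t] - rad):min(imageSize, py[t] + rad)
    cc <- max(1L, px[t] - rad):min(imageSize, px[t] + rad)
    for (r in rr) for (co in cc)
      if ((r - py[t])^2 + (co - px[t])^2 <= rad^2) f[r, co] <- 1
    frames[, , 1L, t] <- f
  }
  list(frames = frames, states = states)
}

#' Periodic articulated-shape video
#'
#' A white disc orbits the frame centre while a bar flaps through the cycle;
#' frame \code{t} equals frame \code{t + period} exactly.
#'
#' @param nFrames total frames (multiple of period).
#' @param period cycle length in frames.
#' @param imageSize frame edge in pixels.
#' @return array (imageSize x imageSize x 1 x nFrames).
#' @export
periodicVideo <- function(nFrames = 64L, period = 32L, imageSize = 32L) {
  if (nFrames %% period != 0L) stop("period must divide nFrames")
  half <- imageSize / 2
  mk <- function(phase) {
    f <- matrix(0, imageSize, imageSize)
    ang <- 2 * pi * phase / period
    cy <- half + 0.62 * half * sin(ang)
    cx <- half + 0.62 * half * cos(ang)
    rad <- max(1, round(imageSize / 10))
    for (r in seq_len(imageSize)) for (co in seq_len(imageSize))
      if ((r - cy)^2 + (co - cx)^2 <= rad^2) f[r, co] <- 1
    # flapping bar through the centre
    wing <- round(half * abs(sin(ang / 2)) * 0.9)
    if (wing > 0) {
      rows <- max(1, round(half) - wing):min(imageSize, round(half) + wing)
      f[rows, round(half)] <- 0.7
    }
    f
  }
  cyc <- lapply(seq_len(period) - 1L, mk)
  out <- array(0, c(imageSize, imageSize, 1L, nFrames))
  for (t in seq_len(nFrames)) out[, , 1L, t] <- cyc[[(t - 1L) %% period + 1L]]
  out
}

#' Distinct glyph exemplars
#'
#' Generates \code{perClass} variants of \code{nClasses} glyph classes
#' (interference patterns of class-specific gratings with seeded
#' variant-specific perturbations) and verifies that all exemplars quantize
#' to pairwise-distinct whole-image codes under the demo codec settings;
#' collisions trigger regeneration with the next seed (error after 10
#' attempts).
#'
#' @param nClasses,perClass class and variant counts.
#' @param imageSize frame edge in pixels.
#' @param seed integer seed.
#' @param blockShape,nLevels,maxVectors demo codec settings used for the
#'   distinctness check.
#' @return list with \code{frames} (imageSize x imageSize x 1 x n),
#'   \code{labels} (integer per exemplar).
#' @export
glyphImages <- function(nClasses = 10L, perClass = 13L, imageSize = 32L,
                        seed = 1L, blockShape = c(8L, 8L), nLevels = 7L,
                        maxVectors = 16L) {
  n <- nClasses * perClass
  xg <- matrix(rep(seq_len(imageSize), each = imageSize), imageSize)
  yg <- matrix(rep(seq_len(imageSize), times = imageSize), imageSize)
  for (attempt in seq_len(10L)) {
    set.seed(seed + attempt - 1L)
    frames <- array(0, c(imageSize, imageSize, 1L, n))
    labels <- integer(n)
    i <- 0L
    for (k in seq_len(nClasses)) {
      fk <- 0.15 + 0.05 * k
      phk <- runif(2L, 0, 2 * pi)
      for (j in seq_len(perClass)) {
        i <- i + 1L
        labels[i] <- k
        ph <- phk + 0.25 * j
        img <- sin(fk * xg + ph[1L]) + cos((fk + 0.07 * (j %% 3L)) * yg + ph[2L]) +
          0.8 * sin(0.08 * k * (xg + yg) + 0.31 * j)
        img <- (img - min(img)) / (max(img) - min(img))
        img <- round(img * 4) / 4  # posterized strokes
        frames[, , 1L, i] <- img
      }
    }
    part <- fitPartition(frames, blockShape, R = 1L)
    cds <- lapply(seq_len(nGroups(part)), function(g)
      fitCodec(blockMatrix(frames, part, g), maxVectors, nLevels))
    obs <- encodeFrames(frames, part, cds, breaks = seq_len(n))
    codes <- do.call(rbind, lapply(obs@idx, function(m) m))
    keys <- apply(codes, 2L, paste, collapse = ",")
    if (!anyDuplicated(keys))
      return(list(frames = frames, labels = labels))
  }
  stop("failed to generate quantization-distinct glyphs in 10 attempts")
}

#' Chirp-event tone sequence
#'
#' Concatenates linear chirps (one per event row: f0, f1, duration in
#' seconds) with Hann onset/offset ramps.
#'
#' @param events matrix or data.frame with columns f0, f1, dur.
#' @param sr sample rate (Hz).
#' @return numeric waveform.
#' @export
toneSequence <- function(events, sr = 8000) {
  events <- as.matrix(events)
  out <- numeric(0)
  for (i in seq_len(nrow(events))) {
    n <- round(events[i, 3L] * sr)
    tt <- (seq_len(n) - 1L) / sr
    f <- events[i, 1L] + (events[i, 2L] - events[i, 1L]) * tt / max(tt)
    phase <- 2 * pi * cumsum(f) / sr
    env <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))
    out <- c(out, sin(phase) * env)
  }
  out
}
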