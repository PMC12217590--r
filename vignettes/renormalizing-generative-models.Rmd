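---
title: "Renormalizing generative models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renormalizing generative models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgm)
```

## The model

`rgm` implements hierarchical discrete state-space generative models with
latent *paths*: generalized partially observed Markov decision processes in
which transitions among the hidden states of a factor depend on a path
variable, and in which a state at one level generates the *initial state*
and *path* of each of its child factors at the level below. Because one
parent step spans `R` child steps, higher levels evolve more slowly; a model
with two pairwise temporal coarse-grainings has top-level states ("events")
that each generate four first-level time steps. Every tensor — the
outcome likelihoods `A`, the transition slices `B`, the inter-level
initial-state and path mappings `D` and `E`, and the top priors — is held as
Dirichlet counts; normalizing the counts over the outcome axis gives the
categorical distributions, and taking the digamma expectation
`psi(a) - psi(sum a)` gives the expected log-probabilities used in message
passing.

Children of distinct factors never overlap (the grouping is a partition),
so every inter-level mapping is a small matrix and belief propagation
reduces to products of small dot products.

## Fast structure learning

Structure is learned in one deterministic pass, without gradient descent:

1. **Quantize.** Frames are tessellated into pixel blocks; each block's
   stacked training vectors (colour and `R` consecutive frames
   concatenated) are reduced by an SVD basis and the singular variates are
   quantized on a uniform, zero-centred grid with an odd number of levels,
   so zero is always a bin centre. Components are retained while their
   relative singular value exceeds `1/64` (configurable) up to a cap;
   constant blocks retain none. Among linear rank-`k` codecs the SVD basis
   minimizes summed squared reconstruction error, which is verified in the
   tests against random orthonormal bases.
2. **Record unique states.** Each group's unique symbol combinations become
   one-hot likelihood columns, in order of first appearance.
3. **Record unique transitions.** Observed successor relations are written
   into transition slices; when a source state has several distinct
   successors, each gets its own path slice (first-appearance order). For
   ascents with `R > 2`, a single slice must explain all transitions inside
   a segment.
4. **Coarse-grain.** Time is partitioned into segments of `R` steps; the
   (initial state, path) pair of each child over a segment becomes one
   super-symbol, neighbouring groups are merged, and the procedure repeats
   until a single factor remains. Top-level transitions are recorded per
   step.

The result is lossless: generating from the inferred top trajectory
reproduces the training sequence exactly, which the tests assert for every
fixture. Episode breaks (chain boundaries, one break per static exemplar)
ensure no transition is ever recorded across concatenated segments —
concatenation artifacts would otherwise fabricate dynamics.

Growth under streaming ingestion can be gated: a new latent cause is
accepted only when the change in the (one-hot posterior) evidence bound
plus the change in negative parameter expected free energy is positive
(`gateGrowth`). Batch structure learning appends all unique instances.

## Inference

Within a segment, the posterior over the trajectory and path is computed
*exactly* per path slice by forward–backward recursions, with the path
posterior proportional to the prior times each slice's evidence. These are
the fixed points of the variational updates; the iterative mean-field
counterpart is exposed as `vmpFixedPoint`, whose free-energy trace is
non-increasing across sweeps (asserted at 1e-9). We use the structured
(exact) form in `infer` because the acceptance checks require posterior
marginals to match brute-force enumeration to 1e-6, which a fully
factorized mean field cannot achieve.

Levels exchange messages on the separation-of-timescales schedule: each
level completes `R` child segments per own step (ascending evidence
messages), the top level runs an exact forward–backward chain with per-step
path marginalization (episodes reset at breaks, no smoothing across them),
and the optional top-down pass returns smoothed expectations everywhere.
Missing or imprecise outcomes are uniform likelihood vectors and contribute
exactly zero to the log-domain messages; padding to a whole number of top
steps uses the same convention.

The per-level free energies reported in a `Posterior` are the negative log
evidences of that level's segments under the posterior-predictive prior
messages from the level above; `logZ` is the exact total log evidence
(`-logZ` the total free energy, `logZ` the ELBO). For a floor of zero and a
model holding `N` equiprobable exemplars, observing one exemplar gives an
ELBO of exactly `-log(N)`, a closed form the tests use.

Ascending messages use the digamma (expected-log) form of the floored
count tensors; with a floor of zero they fall back to plain logs of the
normalized columns, the infinite-count limit.

## Active learning and Bayesian model reduction

Likelihood counts are updated as actions: the increment is the outer
product of outcome and parent-state expectations (unit mass per modality
per step), scored by the parameter expected free energy
`G(a) = -MI(a) - cost(a, c)`. The expected-cost term uses the digamma
expectation of the preference counts and is measured *relative to flat
preferences*, so `G = -MI` exactly when `c` is uniform; constant shifts
cancel in every comparison between an updated and a non-updated tensor.
`G` is computed both from the count algebra and from the normalized joint
(mutual information by exhaustive summation); the two routes agree to 1e-6
on enumerated small tensors and serve as mutual cross-checks.

The commitment probability is the two-action softmax
`P(u1) = softmax(-alpha * c(G0, G1))[2]` with `alpha = 512` by default for
the glyph demonstration; as `alpha` grows the Bayesian model average
becomes model selection. `activeLearn` commits an increment only when the
expected free energy of the *committed* tensor does not increase, which
makes the mutual-information trace monotone by construction; convergence is
declared when the windowed mean MI gain falls below 1e-3 nats over 32
exemplars (both configurable) — the asymptote provides the stopping rule.

Bayesian model reduction evaluates a reduced prior post hoc from
posterior counts via log-beta algebra:
`dF = lnB(post) + lnB(reduced) - lnB(prior) - lnB(post + reduced - prior)`.
On conjugate examples this equals the difference of directly computed log
evidences (asserted at 1e-8). Note that when the posterior equals the
prior the expression collapses to zero — no data were assimilated, so no
reduction can gain or lose evidence.

## Planning, inductive inference and play

Expected free energy per path decomposes as
`G = risk + ambiguity - novelty`: risk is the KL divergence from the
predictive outcome distribution to the preference distribution (capped at
32 nats where preferences put zero mass on a supported outcome), ambiguity
the expected conditional outcome entropy, and novelty the count-based
information gain `0.5 * (1/a - 1/a0)` averaged under the predictive
distribution.

Inductive inference iterates the allowable transitions backwards from
rewarded events (an edge is a path slice with normalized probability above
1e-3 and a recorded count): `inductiveReachability` returns, for every
event, the minimal number of events to a reward, `Inf` when precluded; it
matches an independent breadth-first search exactly on random digraphs.
`planNextEvent` gives precluded successors a -32 nat log-prior rather than
literal zero, keeping the softmax well defined, and falls back to the
uniform prior (with a warning) when everything is precluded.

During play the agent recognizes the current event through the
*action-independent* content of its observations — the paddle row is
masked, because it only reports the consequences of the agent's own action
— then selects the next event through the inductively constrained prior
(preferring successors whose recorded continuations are long), and realizes
that event's paddle trajectory: the action whose immediate outcome best
matches the predicted paddle position is taken (or sampled, under the
shaky-hand probability `stickyP`). When an event has no recorded
continuation or execution has diverged, the agent waits, emitting the stay
action and sliding its event clock one frame at a time, until it
recognizes an event inside the attracting set again; because every
training segment terminates in a hit, any recognized event's predictions
lead to a hit. Optional continual learning accumulates unit Dirichlet
counts along recognized events, which sharpens the digamma-expected
likelihoods and raises the ELBO as play proceeds.

## Synthetic worlds

All experiments run on generated fixtures; nothing is downloaded.

* **Glyphs** (digit stand-ins): 13 variants of 10 classes of posterized
  interference patterns, verified to quantize to 130 pairwise-distinct
  whole-image codes under the demo codec (8x8 blocks, 7 levels, at most 16
  singular vectors); collisions trigger regeneration with the next seed.
* **Periodic video** (dove stand-in): a 64-frame, period-32
  articulated-shape cycle, encoded with two-frame voxels and one pairwise
  ascent, compressing to 8 events of 4 frames; 128 generated frames cycle
  the orbit exactly four times.
* **Lorenz video**: Euler–Maruyama integration of the Lorenz system
  (sigma 10, rho 28, beta 8/3; frame step 0.02 in four substeps; state
  noise 2 per unit time) rendered as a white disc over a faint
  dotted-trajectory backdrop, the attractor wings filling about 80% of the
  frame. 512 frames under eight-fold coarse-graining give 64 top events,
  all unique — chaos never repeats an 8-frame segment at this resolution.
  The noiseless integrator is checked against an independent ODE solver.
* **Pong / Breakout**: a 12x9 cell grid; each cell is one observation
  factor over a small categorical alphabet (background, ball, three paddle
  parts, and targets in Breakout), which is the direct symbolic observation
  path; `renderFrames` expands cells to 32x32 colour tiles when the pixel
  path is wanted. The ball moves diagonally with elastic reflection; the
  paddle moves one column per step. Breakout removes the lowest remaining
  target row on a hit and resets on the golden row, re-centring the paddle
  and re-serving from a seeded location around the centre.
* **Tones**: concatenated linear chirps for the time-frequency frontend,
  whose Morlet transform uses a frequency-independent 32 ms Gaussian
  envelope over log-spaced centre frequencies (effectively a short-term
  Fourier transform); the inverse accumulates per-bin analytic phase under
  interpolated magnitude envelopes.

What the fixtures do *not* emulate: natural image statistics (the glyphs
are low-entropy patterns, so codec alphabets stay small), sensor noise in
the video fixtures, or reverberant/polyphonic audio. Passing tests
therefore demonstrate the machinery — lossless compression, exact
inversion, gated learning, inductive planning — not robustness to natural
data.

## Conditions of the game experiments

Three choices deserve explanation because the qualitative claims depend on
them.

* **Pong does not reset its paddle on a miss** (Breakout does, along with
  its targets). The ball's hit-to-hit trajectories ("legs") form a
  deterministic 11-leg cycle per parity class, and never-missing play must
  replay every leg of its cycle; legs landing at the edge columns only
  enter the training set if the freely wandering paddle happens to be
  there. A paddle re-centred after every miss essentially never covers
  them.
* **The random-play pool uses serially correlated actions** (the previous
  action repeats with probability 0.7) for the play demonstrations. An
  uncorrelated paddle stays close to its starting column for the duration
  of a leg, and edge legs again never enter the training set; a persistent
  random walk spreads across the field. The event-count experiment is
  still run under i.i.d. uniform actions.
* **Segment ingestion is novelty-first**: chains contributing ball content
  not yet covered are ingested before repeats, an instance of
  expected-free-energy data selection — repeats add no information at
  fixed budget. Chains are trimmed at their *start* to a whole number of
  events so every chain ends exactly at its final hit.

With these conditions a 60,000-frame pool covers both leg cycles within
the 1,024-frame training budget, and deterministic play yields zero misses
over 512 steps; under the shaky hand the agent diverges occasionally and
recovers through the waiting behaviour.

## Numerical choices

* Count floor: 1/32 by default, 1/128 for the game models; stored on the
  model and applied lazily, so losslessness is testable at floor zero.
* Zero columns normalize to uniform, keeping generation defined for states
  never visited.
* All message arithmetic is log-domain with max-subtraction; `-36` stands
  in for log zero in the floor-zero limit.
* Quantization bins span the +/- maximum absolute training variate per
  component; ties in `which.max` resolve to the first index, so argmax
  generation is deterministic.
* Fixed-point sweeps in `vmpFixedPoint` stop at `|dF| < 1e-4` nats or 16
  sweeps.
* Trailing steps that do not fill a segment are dropped with a warning;
  padding would fabricate transitions. Episode breaks must align with
  segment boundaries, which the fixtures guarantee by construction.

## Problem sizes

The shipped experiments are sized for a single CPU core: 130 glyph
exemplars at 32x32, 64- and 512-frame videos at 32x32, a 21,280-frame
uniform-play pool for the event-count experiment, a 60,000-frame
persistent-play pool for the play experiments, and 512-step episodes.
The complete test suite, including the end-to-end checks, runs in a few
minutes.

## Serialization

A model container is a directory holding a human-readable `manifest.json`
(shapes, grouping, temporal factors, codec metadata, format version) and a
single `arrays.rds` with every count tensor and codec matrix at full
precision; the round trip is bit-exact and version mismatches or corrupted
files fail loudly.

## Limitations

Models are brittle by design: they recognize only content whose discrete
codes they have seen, and the game agent plays expertly only within the
attracting set carved out by its selected training data. The audio inverse
is a magnitude-only resynthesis (analytic phase, no phase recovery), fine
for stereotyped calls, not for arbitrary audio. Spatial merging supports
row-major grids (2x2) and arbitrary explicit partitions, not learned
groupings. Weight sharing across groups is deliberately not imposed.
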