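Package: rgm
Title: Renormalizing Generative Models for Discrete State-Space Active Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical discrete state-space generative models with latent
    paths (generalized partially observed Markov decision processes), built by
    fast structure learning: recursive coarse-graining of quantized
    observations over space and time. Provides block-SVD image quantization
    and a Morlet time-frequency frontend, exact structured variational
    message passing with a separation of temporal scales, expected-free-energy
    gated active learning of Dirichlet likelihoods, Bayesian model reduction,
    inductive planning by backward reachability over event graphs, and
    synthetic environments (glyph images, periodic and chaotic videos,
    grid-world Pong and Breakout) for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'tensor-ops.R'
    'serialize.R'
    'frontend-image.R'
    'frontend-audio.R'
    'structure.R'
    'inference.R'
    'learning.R'
    'planning.R'
    'worlds.R'
    'games.R'
    'demos.R'
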