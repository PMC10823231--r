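Package: encmanifold
Title: Neural Encoding Manifolds from Population Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Organizes a recorded population of visual neurons on a
    low-dimensional "encoding manifold" in which each point is a neuron and
    proximity means similar stimulus selectivity and response dynamics.
    Spike trains recorded under a factorial ensemble of drifting gratings
    and optical-flow stimuli are binned into trial-averaged response maps
    and assembled into a nonnegative neurons x stimuli x time tensor; a
    nonnegative canonical polyadic (CP) tensor factorization with rank
    selection yields per-neuron encoding vectors; an iterated adaptive
    neighborhood kernel builds a weighted data graph over neurons; and
    diffusion maps infer the manifold. Companion tools quantify whether
    the manifold is clustered or continuous (density-based hierarchical
    clustering, local intrinsic dimensionality, adjacency ordering,
    like-type local density), compute stimulus-selectivity indices and
    response-significance calls, estimate receptive fields by
    spike-triggered averaging with 2-D Gaussian fits and mosaic
    statistics, and simulate every validation input (ring-attractor
    populations, stochastic block models, discrete-type and continuum
    populations, linear-nonlinear model neurons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust,
    withr
Config/testthat/edition: 3
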