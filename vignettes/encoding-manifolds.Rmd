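---
title: "Inferring neural encoding manifolds from population spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring neural encoding manifolds from population spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most low-dimensional analyses of visual population recordings take a
*stimulus* perspective: each point in the embedding is a trial, and the
question is how well the stimulus can be decoded from the population state.
This package takes the complementary *neuron* ("encoding") perspective.
Each point is a neuron; two neurons are close when they respond with
similar dynamics to similar stimuli across a factorial ensemble of drifting
gratings and optical flows. The shape of the resulting manifold then says
something about the functional architecture of the circuit itself: a
population of discrete cell types (as in the retina, where each ganglion
cell type tiles space with its own mosaic) should produce well-separated
clusters, while a richly interconnected cortical circuit can produce a
continuum in which selectivity varies smoothly from neighborhood to
neighborhood. Convolutional networks, whose units share weights within
feature maps, sit at the clustered extreme. The package implements the
full inference pipeline, statistics that quantify clustered-versus-
continuous topology, and simulators for every validation input.

## The pipeline

Spike trains are binned into trial-averaged response maps: for each neuron
and each of the 6 stimulus conditions, a directions x time matrix of
firing rate (`bin_psth()`). Rates are normalized per neuron to unit peak
(`normalize_maps()`), preserving the nonnegativity the factorization
requires, and optionally each neuron's direction axis is circularly
rotated so its preferred direction sits at slot 1 (`align_directions()`).
The alignment — one shift per neuron, shared across conditions — factors
out direction preference so that neurons are compared by tuning shape and
dynamics rather than absolute preferred angle; it is recorded and
invertible. The aligned maps are flattened into a nonnegative tensor
`neurons x (condition, relative direction) x time` (`build_tensor()`;
with the default ensemble, 48 stimulus slots by 25 bins of 50 ms).

**Stage 1** (`ntf_decompose()`) is a nonnegative canonical polyadic (CP)
decomposition: the tensor is approximated by a sum of `R` rank-1
components, each an outer product of a neuron-loading vector, a stimulus
profile, and a temporal profile. We fit it with hierarchical alternating
least squares (HALS) under nonnegativity, minimizing squared error, with
up to 500 sweeps and a convergence tolerance of 1e-8 on the relative
error. The objective is nonconvex, so each restart screens several random
initializations for a few sweeps and continues the most promising one;
the best of `n_restarts` restarts is returned. Stimulus and temporal
factors are normalized to unit L2 per component, so all magnitude lives
in the neuron loadings and row `i` of the neuron-factor matrix is the
encoding vector of neuron `i`.

The rank is selected by `select_rank()`: the smallest candidate `R` whose
error drop to `R + 1` falls below `eps_elbow = 0.01` while the
cross-restart stability — mean Hungarian-matched cosine of neuron factors
across restarts (`factor_stability()`) — is at least `s_min = 0.9`. The
elbow uses the absolute drop of the relative error (both live on [0, 1]);
a ratio would be numerically meaningless once the error reaches zero at
the true rank. When no candidate qualifies, the rank maximizing
`stability * (1 - error)` is returned with a warning.

**Stage 2** builds a weighted graph over neurons in factor space
(`build_graph()`): a self-tuning Gaussian kernel
`w_ij = exp(-d_ij^2 / (sigma_i sigma_j))` with `sigma_i` the distance to
the `k`-th neighbor (`k = 10`), starting from each point's `k` nearest
neighbors and iteratively pruning edges whose weight falls below
`theta = 0.1` of the point's median retained weight (at most 5 passes, or
until a fixed point). The pruning removes edges that straddle density
gaps, so distinct types disconnect cleanly. Neighborhoods are symmetrized
with the maximum rule, which preserves a connection found from either
endpoint.

`diffusion_map()` embeds the graph: the kernel is density-normalized with
exponent `alpha = 1` (the Laplace–Beltrami normalization, making the
embedding insensitive to sampling density), row-normalized to a Markov
operator, and the top `m = 10` nontrivial right eigenvectors, scaled by
`lambda^t` (`t = 1`), are the diffusion coordinates. The globally
constant eigenvector is dropped. On a disconnected graph the unit
eigenvalue has multiplicity equal to the number of components; we keep
the remaining unit-eigenvalue eigenvectors as coordinates — computed
deterministically as component indicators orthogonalized against the
constant — because they are exactly what separates the components in the
embedding, and we report the multiplicity and component labels alongside.
Eigenvector signs are fixed by making each vector's largest-magnitude
entry positive, so runs are reproducible bit-for-bit.

## Quantifying topology

`density_cluster()` decides whether the manifold is clustered or
continuous. It is a condensed-tree density clustering in the HDBSCAN
family: mutual-reachability distances (with core distance at the
`min_cluster_size`-th neighbor) are single-linkage clustered, splits
smaller than `min_cluster_size` (default `max(5, N/100)`) are discarded
as fall-outs, and flat clusters maximize density persistence (excess of
mass) over the condensed tree. Two choices matter in practice and are
exposed as arguments:

* **Cluster-selection epsilon.** Dendrogram heights below a minimum split
  scale (default 20% of the median pairwise distance) are treated as one
  density level. Without this floor, near-duplicate embedding coordinates
  make density persistence diverge and excess-of-mass always prefers
  micro-clusters; with it, structure finer than a fifth of the global
  scale is never reported as separate clusters. The default is robust
  over at least 0.15–0.25 on the package's simulators.
* **Clustering diffusion time.** At `t = 1` the internal eigenmodes of a
  tight, disconnected cluster have the same coordinate scale as the
  indicators that separate clusters, so no geometric gap exists in the
  raw coordinates. For clustering (only), coordinates are rescaled to a
  longer diffusion time chosen so the smallest kept eigenvalue is damped
  to 0.1, letting the slow, cluster-separating modes dominate.

The root of the condensed tree competes for selection like any other
cluster (birth at its first split), so a connected, uniformly sampled
sheet is reported as one cluster rather than as noise. The verdict is
"clustered" when at least two clusters exist and no single cluster holds
80% of the points, "continuous" otherwise.

`local_intrinsic_dim()` is the Levina–Bickel maximum-likelihood estimator
from nearest-neighbor distance ratios (`k = 15`), invariant to global
rescaling, with distances floored at 1e-9 of the mean pairwise distance
to survive duplicates. `like_type_density()` scores the edge-weighted
fraction of same-labeled neighbors, `order_adjacency()` permutes the
weight matrix into label blocks (reporting the share of weight inside the
diagonal blocks), and `topology_summary()` bundles everything into one
report.

## Selectivity and receptive fields

Selectivity indices operate on *un-normalized* maps and are ratios of
mean evoked rates, hence invariant to rescaling a neuron's rate:
grating-versus-flow `(G - F)/(G + F)`; contrast polarity
`(P - N)/(P + N)` over positive/negative flows; OSI and DSI as the first
and second circular moments of the 8-point direction tuning curve of the
best condition (invariant to circular shifts, consistent with the
alignment step); distributed selectivity as the normalized entropy of the
six condition means. Response significance compares each condition's
total evoked spike count against a supplied scalar baseline rate with a
one-sided exact Poisson tail, Benjamini–Hochberg corrected across the six
conditions. With a scalar baseline there are no trials to permute; the
exact tail is the corresponding conservative null, and its false-positive
rate is at most alpha by construction (verified on 1,000 simulated null
neurons in the tests). `population_fractions()` reports the fraction of
neurons responsive to the low spatial-frequency grating and
orientation-tuned (OSI at least 0.5 by default), and the fraction whose
sole significant condition is that grating.

Receptive fields are estimated by the spike-triggered average of a binary
checkerboard (frames every 33 ms; 15 lags, about 500 ms of history) and
summarized by an elliptical 2-D Gaussian fit (Levenberg–Marquardt;
initialized from the centroid and second moments of the thresholded
magnitude; polarity from the dominant peak). The Gaussian includes an
orientation term — the elliptical form subsumes the circular one, at the
cost of two parameters. `mosaic_stats()` summarizes how a set of fits
tiles space: coverage factor, nearest-neighbor distance statistics
(regular mosaics have a low coefficient of variation; matched-density
Poisson centers a high one), and the fraction of cells overlapping their
nearest neighbor at the 1-SD contour, using each fit's effective circular
radius `sqrt(sd_major * sd_minor)` since ellipse-pair intersection has no
closed form.

## Simulators: what they emulate, and what they do not

`simulate_ring()` implements the threshold-linear ring attractor:
`tau dm_i/dt = -m_i + [h_i + (1/N) sum_j (J2 cos(theta_i - theta_j) - J0) m_j]_+`,
uniform inhibition `J0` plus cosine-modulated excitation `J2` on the
direction circle, with tuned input
`h = c (1 - eps + eps cos(theta - theta_stim))`. Defaults `J0 = 4`,
`J2 = 8`, `tau = 20` ms, `c = 2`, `eps = 0.3` put the network in a
strongly modulated marginal regime: an untuned input still forms a bump
(the hallmark of the marginal phase), and the equilibrium bump has a
half-width of roughly 34 degrees, comparable to cortical orientation
tuning. Divergent parameter sets are detected at integration time and
rejected with an error naming the inhibition/excitation imbalance. Each
of the 8 stimulus directions is integrated to equilibrium (Euler, 1-ms
steps) and combined with a single shared saturating temporal kernel, so
all neurons differ only in tuning — the setting in which the stimulus
axis alone should drive the factorization, and eight latent components
emerge for eight directions. We use 64 neurons and no noise for this
demonstration.

`generate_population()` produces the discrete / continuum / feature-map
regimes from six stock condition-direction-time templates (unit peak;
one type carries a delayed response to positive-contrast flows, one
responds solely to the low-SF grating, one is direction-tuned). Discrete
neurons copy one template; continuum neurons interpolate smoothly among
the templates along 1–3 uniform latent variables; feature-map templates
have disjoint condition and time support, so their cross-correlation is
near zero. Every neuron gets a random preferred direction (a circular
shift the alignment step later removes), and rectified Gaussian noise
with SD 0.1 of the template peak — a deliberate simplification: noise is
independent across bins and neurons, with none of the trial-to-trial
correlation, adaptation, or rate nonstationarity of real recordings.
Passing tests on these populations therefore demonstrates that the
pipeline recovers the intended organization under known, favorable
conditions; it does not certify performance on real data.

`generate_sbm()` samples stochastic block models for the
connectivity-to-topology demonstrations, and `simulate_ln_neurons()`
drives Gaussian-times-biphasic linear-nonlinear neurons with the
checkerboard to validate the STA machinery (rates rectified at a
baseline, inhomogeneous Poisson spiking).

## Numerical choices and degenerate inputs

* All-zero tensors factor to the zero model with relative error defined
  as 0; all-zero neurons are flagged (`silent`) and left at zero by
  normalization.
* Identical points get kernel weight 1 and form complete graph
  neighborhoods; bandwidths are floored at 1e-12.
* Alignment ties (equal summed response in several directions) go to the
  lowest direction index.
* Components of the CP model are ordered by decreasing neuron-factor
  norm; Hungarian assignment breaks matching ties deterministically.
* Diffusion eigenvalues are clipped to [-1, 1]; negative eigenvalues are
  raised to integer powers safely via `sign(lambda) |lambda|^t`.
* Problem sizes in the test suite: ring demos use 64 neurons; population
  contrasts use 600 neurons x 48 stimuli x 25 bins with rank 8 and 3
  restarts; STA validation uses 30 simulated minutes of 16 x 16
  checkerboard at 33-ms frames.

## Known limitations

* The two-stage pipeline assumes a factorial, direction-balanced
  ensemble; conditions must share duration, trial count and direction
  grid.
* Rank selection inherits the nonconvexity of the factorization: on
  tensors whose nonnegative rank exceeds their multilinear structure,
  restarts can populate distinct near-global optima and depress the
  stability score. The warm-started restarts mitigate but cannot
  eliminate this.
* The significance test treats the baseline rate as known; uncertainty
  in an estimated baseline is not propagated.
* Serialization uses CSV/JSON throughout; factor models and embeddings
  are exact to double-precision text round-off.
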