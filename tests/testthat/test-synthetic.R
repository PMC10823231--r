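test_that("ring responses are circularly equivariant in the stimulus direction", {
  ring <- simulate_ring(n_neurons = 32, seed = 5)
  eq <- ring$equilibria   # neurons x 8 directions, both on 45-degree grids
  ## rotating the stimulus by one step (45 deg) rotates the population
  ## response by one neuron-grid step (32/8 = 4 neurons): neuron i under
  ## stimulus d+1 responds like neuron i-4 under stimulus d. Tolerance
  ## reflects the finite integration horizon from a common (asymmetric)
  ## initial condition.
  rot <- function(v, k) c(v[(length(v) - k + 1):length(v)], v[1:(length(v) - k)])
  for (d in 1:7) {
    expect_equal(eq[, d + 1], rot(eq[, d], 4), tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
  ## every neuron peaks at (or adjacent to) its preferred direction
  peak_dir <- apply(eq, 1, which.max)
  pref_slot <- round(ring$preferred_deg / 45) %% 8 + 1
  circ_gap <- pmin(abs(peak_dir - pref_slot), 8 - abs(peak_dir - pref_slot))
  expect_true(all(circ_gap <= 1))
})

test_that("the marginal-regime ring forms a reproducible bump under untuned input", {
  r1 <- simulate_ring(input_tuning = 0, seed = 7)
  r2 <- simulate_ring(input_tuning = 0, seed = 7)
  expect_equal(r1$equilibria, r2$equilibria)
  prof <- r1$equilibria[, 1]
  ## bump: strong modulation, localized support
  expect_gt(max(prof), 0)
  expect_lt(min(prof), 0.05 * max(prof))
  ## unstable parameters are rejected with the stability condition named
  expect_error(simulate_ring(J0 = 0, J2 = 20, seed = 1), "stable|diverged")
})

test_that("ring maps share one temporal profile and spikes can be emitted", {
  ring <- simulate_ring(n_neurons = 16, n_trials = 5, spikes = TRUE, seed = 8)
  r <- ring$maps$rates
  ## identical temporal dynamics: every (neuron, direction) time course is
  ## proportional to the same kernel
  ref <- r[1, 1, which.max(ring$equilibria[1, ]), ]
  for (i in c(2, 9)) {
    d <- which.max(ring$equilibria[i, ])
    expect_gt(cor(ref, r[i, 1, d, ]), 1 - 1e-10)
  }
  expect_s3_class(ring$spikes, "spike_data")
  ## spike emission is seed-reproducible
  ring2 <- simulate_ring(n_neurons = 16, n_trials = 5, spikes = TRUE, seed = 8)
  expect_equal(ring$spikes$spikes, ring2$spikes$spikes)
})

test_that("SBM edge counts and densities match their probabilities", {
  ## deterministic case: 3 fully connected blocks of 10
  sb <- generate_sbm(30, 3, p_in = 1, p_out = 0, seed = 9)
  expect_equal(sum(sb$adjacency) / 2, 3 * choose(10, 2))
  expect_equal(max(graph_components(sb$adjacency)), 3)
  expect_true(all(sb$adjacency == t(sb$adjacency)))
  expect_true(all(diag(sb$adjacency) == 0))
  ## stochastic case: empirical densities within 3 SE
  sb2 <- generate_sbm(300, 3, p_in = 0.5, p_out = 0.05, seed = 10)
  same <- outer(sb2$blocks, sb2$blocks, `==`)
  ut <- upper.tri(sb2$adjacency)
  nw <- sum(ut & same); nb <- sum(ut & !same)
  pw <- mean(sb2$adjacency[ut & same])
  pb <- mean(sb2$adjacency[ut & !same])
  expect_lt(abs(pw - 0.5), 3 * sqrt(0.25 / nw))
  expect_lt(abs(pb - 0.05), 3 * sqrt(0.05 * 0.95 / nb))
  ## p_out = p_in is indistinguishable from Erdos-Renyi: within- and
  ## between-block degrees have equal means (Monte Carlo, 3 SE)
  sb3 <- generate_sbm(300, 3, p_in = 0.2, p_out = 0.2, seed = 11)
  same3 <- outer(sb3$blocks, sb3$blocks, `==`)
  ut3 <- upper.tri(sb3$adjacency)
  d_in <- mean(sb3$adjacency[ut3 & same3]); d_out <- mean(sb3$adjacency[ut3 & !same3])
  expect_lt(abs(d_in - d_out), 3 * sqrt(0.16 / sum(ut3 & !same3)))
  expect_error(generate_sbm(30, 3, p_in = 0.2, p_out = 0.5), "p_out")
})

test_that("population generators are reproducible and validate their specs", {
  p1 <- generate_population("discrete", 60, K = 6, seed = 12)
  p2 <- generate_population("discrete", 60, K = 6, seed = 12)
  expect_equal(p1$maps$rates, p2$maps$rates)
  expect_error(generate_population("discrete", 4, K = 6), "K > n_neurons")
  expect_identical(sort(unique(p1$labels)), 1:6)
})

test_that("noiseless discrete types collapse to identical factor rows and disconnect", {
  pop <- generate_population("discrete", 120, K = 4, noise_sd = 0, seed = 13)
  tens <- build_tensor(align_directions(normalize_maps(pop$maps)))
  m <- suppressWarnings(ntf_decompose(tens, 6, n_restarts = 2, seed = 1,
                                      max_iter = 2000, tol = 1e-12))
  for (k in 1:4) {
    rows <- m$neuron_factors[pop$labels == k, , drop = FALSE]
    spread <- max(apply(rows, 2, function(z) diff(range(z))))
    expect_lt(spread, 1e-4 * max(1, max(rows)))
  }
  g <- build_graph(m, k = 10)
  expect_true(all(g$weights[pop$labels == 1, pop$labels == 2] == 0))
  expect_equal(max(graph_components(g)), 4)
})

test_that("feature-map templates are nearly uncorrelated", {
  pop <- generate_population("feature_map", 120, K = 8, noise_sd = 0.02,
                             seed = 14)
  tpl <- sapply(pop$templates, as.vector)
  cc <- cor(tpl)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("LN spike counts match the integrated rate", {
  stim <- checkerboard_stimulus(6000, 8, 8, seed = 15)
  specs <- data.frame(x0 = 4, y0 = 4, sd = 1.2, polarity = 1, gain = 5,
                      baseline = 8)
  sim <- simulate_ln_neurons(specs, stim, seed = 16)
  mu <- sum(sim$rates[1, ]) * stim$frame_duration
  expect_lt(abs(length(sim$spike_times[[1]]) - mu), 3 * sqrt(mu))
})
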