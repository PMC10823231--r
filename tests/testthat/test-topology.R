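test_that("well-separated Gaussian clusters are recovered exactly", {
  set.seed(31)
  X <- rbind(matrix(rnorm(300, 0), 100, 3),
             matrix(rnorm(300, 8), 100, 3),
             matrix(rnorm(300, -8), 100, 3))
  rep3 <- density_cluster(X, min_cluster_size = 10)
  expect_identical(rep3$n_clusters, 3L)
  expect_equal(adjusted_rand(rep3$cluster_labels, rep(1:3, each = 100)), 1)
  expect_true(all(rep3$cluster_persistence >= 0))
  expect_identical(rep3$verdict, "clustered")
})

test_that("a connected uniform sheet is a single cluster across seeds", {
  for (s in 1:10) {
    set.seed(40 + s)
    Y <- matrix(runif(1000), 500, 2)
    rep1 <- density_cluster(Y, min_cluster_size = 10)
    expect_identical(rep1$n_clusters, 1L)
    expect_gte(rep1$largest_cluster_fraction, 0.9)
    expect_identical(rep1$verdict, "continuous")
  }
})

test_that("degenerate inputs follow the documented conventions", {
  repI <- density_cluster(matrix(1, 30, 2), min_cluster_size = 5)
  expect_identical(repI$n_clusters, 1L)
  expect_warning(repS <- density_cluster(matrix(rnorm(10), 5, 2),
                                         min_cluster_size = 5),
                 "single cluster")
  expect_identical(repS$n_clusters, 1L)
})

test_that("local intrinsic dimension recovers known manifold dimensions", {
  set.seed(32)
  line <- cbind(runif(500), 0, 0)
  d1 <- local_intrinsic_dim(line, k = 15)
  expect_lt(abs(median(d1) - 1), 0.2)
  ball <- matrix(rnorm(2000 * 3), 2000, 3)
  ball <- ball * (runif(2000)^(1 / 3) / sqrt(rowSums(ball^2)))
  d3 <- local_intrinsic_dim(ball, k = 15)
  expect_lt(abs(median(d3) - 3), 0.5)
  th <- runif(500, 0, 2 * pi)
  ring <- cbind(cos(th), sin(th))
  dr <- local_intrinsic_dim(ring, k = 15)
  expect_lt(abs(median(dr) - 1), 0.2)
  ## invariant to global isotropic rescaling
  expect_equal(local_intrinsic_dim(ring * 1000, k = 15), dr)
  expect_error(local_intrinsic_dim(ring, k = 3), ">= 5")
})

test_that("like-type density scores label concentration on the graph", {
  set.seed(33)
  ## all same label -> 1 everywhere
  X <- matrix(rnorm(60), 30, 2)
  g <- build_graph(X, k = 5)
  expect_true(all(like_type_density(g, rep("a", 30)) == 1))
  ## two labels on two disconnected components -> 1 everywhere
  X2 <- rbind(matrix(rnorm(50, 0, 0.5), 25, 2), matrix(rnorm(50, 50, 0.5), 25, 2))
  g2 <- build_graph(X2, k = 5)
  expect_true(all(like_type_density(g2, rep(c("a", "b"), each = 25)) == 1))
  ## random balanced labels on a dense graph -> mean ~ 0.5
  scores <- replicate(20, {
    lab <- sample(rep(0:1, 50))
    mean(like_type_density(build_graph(matrix(rnorm(200), 100, 2), k = 30),
                           lab))
  })
  expect_lt(abs(mean(scores) - 0.5), 0.05)
  ## isolated neuron flagged with score 0
  W <- diag(3); W[1, 2] <- W[2, 1] <- 0.5
  s <- like_type_density(W, c("a", "a", "b"))
  expect_equal(s[[3]], 0)
  expect_true(attr(s, "isolated")[3])
})

test_that("adjacency ordering exposes block structure and round-trips", {
  sb <- generate_sbm(120, 3, p_in = 0.5, p_out = 0.05, seed = 34)
  ord <- order_adjacency(sb$adjacency, sb$blocks)
  ## fraction of weight inside diagonal blocks >= SBM expectation
  p_in <- 0.5; p_out <- 0.05
  expect_gte(ord$block_weight_fraction, p_in / (p_in + 2 * p_out) * 0.9)
  ## permutation round-trip
  inv <- order(ord$permutation)
  expect_equal(ord$weights[inv, inv], sb$adjacency,
               ignore_attr = TRUE)
  ## single cluster: permutation is a degree sort
  W <- matrix(runif(100), 10, 10); W <- (W + t(W)) / 2; diag(W) <- 1
  o1 <- order_adjacency(W, rep(1, 10))
  expect_equal(o1$permutation, order(rowSums(W), decreasing = TRUE))
})

test_that("topology summary separates discrete and continuum regimes", {
  ## scaled-down end-to-end check (the full 10-seed contrast runs in the
  ## acceptance suite): one seed per regime through factor + embedding
  pd <- generate_population("discrete", 240, K = 4, noise_sd = 0.1, seed = 51)
  td <- build_tensor(align_directions(normalize_maps(pd$maps)))
  md <- suppressWarnings(ntf_decompose(td, 8, n_restarts = 2, seed = 1))
  ed <- diffusion_map(build_graph(md, k = 10), m = 10)
  rd <- topology_summary(ed)
  expect_identical(rd$verdict, "clustered")
  expect_gte(adjusted_rand(rd$cluster_labels, pd$labels), 0.9)
  expect_false(is.null(rd$local_dim))

  pc <- generate_population("continuum", 240, latent_dim = 2, noise_sd = 0.1,
                            seed = 51)
  tc <- build_tensor(align_directions(normalize_maps(pc$maps)))
  mc <- suppressWarnings(ntf_decompose(tc, 8, n_restarts = 2, seed = 1))
  ec <- diffusion_map(build_graph(mc, k = 10), m = 10)
  rc <- topology_summary(ec)
  expect_identical(rc$verdict, "continuous")
  expect_gte(rc$largest_cluster_fraction, 0.8)
})
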