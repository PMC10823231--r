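# Shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ring_fixture <- function() {
  fixture("ring", function() {
    ring <- simulate_ring(seed = 1)
    tensor <- build_tensor(normalize_maps(ring$maps))
    list(ring = ring, tensor = tensor)
  })
}

# Small exact low-rank tensors with known factors.
rank1_tensor <- function(seed = 5) {
  set.seed(seed)
  a <- runif(10, 0.2, 1); b <- runif(6, 0.2, 1); cc <- runif(5, 0.2, 1)
  list(X = array(outer(outer(a, b), cc), dim = c(10, 6, 5)),
       A = matrix(a), B = matrix(b), C = matrix(cc))
}

rank3_tensor <- function(seed = 6, n = 30) {
  set.seed(seed)
  A <- matrix(0, n, 3)
  g <- split(seq_len(n), rep(1:3, length.out = n))
  for (r in 1:3) A[g[[r]], r] <- runif(length(g[[r]]), 0.5, 1)
  B <- diag(3)[rep(1:3, each = 2), ] * runif(6, 0.5, 1)
  C <- matrix(runif(15, 0.2, 1), 5, 3)
  X <- array(0, c(n, 6, 5))
  for (r in 1:3) X <- X + array(outer(outer(A[, r], B[, r]), C[, r]), c(n, 6, 5))
  list(X = X, A = A, B = B, C = C)
}

# Un-normalized Poisson response maps with given per-condition rates.
poisson_maps <- function(n, rate_mat, ensemble = default_ensemble(),
                         n_bins = 25, seed = 1) {
  set.seed(seed)
  bw <- ensemble[[1]]$duration / n_bins
  ntr <- ensemble[[1]]$n_trials
  D <- ensemble[[1]]$n_directions
  r <- array(0, c(n, length(ensemble), D, n_bins))
  for (ci in seq_along(ensemble)) {
    lam <- rate_mat[, ci] * bw * ntr
    r[, ci, , ] <- array(stats::rpois(n * D * n_bins, rep(lam, D * n_bins)),
                         c(n, D, n_bins)) / (ntr * bw)
  }
  encmanifold:::new_response_maps(r, bw, ensemble)
}

# Deterministic maps from a rates array.
maps_from_array <- function(rates, ensemble = default_ensemble(),
                            bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- ensemble[[1]]$duration / dim(rates)[4]
  encmanifold:::new_response_maps(rates, bin_width, ensemble)
}

# Synthetic rf_fit for mosaic tests.
make_rf_fit <- function(x, y, s_major = 1, s_minor = s_major) {
  structure(list(center = c(x = x, y = y),
                 sd_axes = c(major = s_major, minor = s_minor),
                 orientation = 0, amplitude = 1, offset = 0,
                 fit_residual = 0, converged = TRUE),
            class = "rf_fit")
}

cycle_adjacency <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
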