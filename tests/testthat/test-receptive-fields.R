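test_that("a single spike's STA is exactly the preceding frames", {
  stim <- checkerboard_stimulus(50, 8, 8, seed = 71)
  t_spike <- 20.5 * stim$frame_duration   # inside frame 21
  sta <- compute_sta(t_spike, stim, n_lags = 5)
  expect_equal(sta$n_spikes, 1L)
  for (lag in 0:4) {
    expect_equal(sta$average[lag + 1, , ], stim$frames[21 - lag, , ])
  }
  expect_error(compute_sta(numeric(0), stim), "spikes")
  expect_error(compute_sta(1e6, stim), "span")
})

test_that("stimulus-independent spikes give a null STA within sampling error", {
  stim <- checkerboard_stimulus(6000, 10, 10, seed = 72)
  set.seed(73)
  spikes <- sort(runif(3000, 0.6, stim$duration))
  sta <- compute_sta(spikes, stim, n_lags = 10)
  se <- 1 / sqrt(sta$n_spikes)   # SD of a mean of +/-1 values
  expect_lt(max(abs(sta$average)), 4.5 * se)
})

test_that("Gaussian fits recover noiseless parameters and handle polarity", {
  xg <- matrix(rep(1:20, each = 16), 16, 20)
  yg <- matrix(rep(1:16, times = 20), 16, 20)
  frame <- 2.5 * exp(-((xg - 12.3)^2 / (2 * 2.2^2) + (yg - 6.7)^2 / (2 * 1.4^2)))
  fit <- fit_gaussian_rf(frame)
  expect_lt(abs(fit$center[1] - 12.3) / 12.3, 0.01)
  expect_lt(abs(fit$center[2] - 6.7) / 6.7, 0.01)
  expect_lt(abs(fit$sd_axes[1] - 2.2) / 2.2, 0.01)
  expect_lt(abs(fit$sd_axes[2] - 1.4) / 1.4, 0.01)
  expect_gt(fit$amplitude, 0)
  ## OFF polarity: same geometry, negative amplitude
  fit_off <- fit_gaussian_rf(-frame)
  expect_lt(fit_off$amplitude, 0)
  expect_equal(fit_off$center, fit$center, tolerance = 1e-6)
  expect_equal(fit_off$sd_axes, fit$sd_axes, tolerance = 1e-6)
  ## translation equivariance
  sh <- cbind(frame[, 3:20], frame[, 1:2] * 0)
  fit_sh <- fit_gaussian_rf(sh)
  expect_equal(fit_sh$center[["x"]], fit$center[["x"]] - 2, tolerance = 0.05)
  expect_equal(fit_sh$center[["y"]], fit$center[["y"]], tolerance = 0.05)
  expect_error(fit_gaussian_rf(matrix(0, 8, 8)), "flat")
})

test_that("LN simulation round-trips through the STA pipeline", {
  ## 10 simulated minutes at 33-ms frames
  stim <- checkerboard_stimulus(18000, 14, 14, seed = 74)
  specs <- data.frame(x0 = c(4.2, 10.6), y0 = c(9.1, 4.4), sd = 1.3,
                      polarity = c(1, -1), gain = 6, baseline = 5)
  sim <- simulate_ln_neurons(specs, stim, seed = 75)
  for (i in 1:2) {
    sta <- compute_sta(sim$spike_times[[i]], stim, n_lags = 15)
    fit <- fit_gaussian_rf(sta$spatial)
    err <- sqrt(sum((fit$center - c(specs$x0[i], specs$y0[i]))^2))
    expect_lt(err, 0.5)
    expect_lt(abs(sqrt(prod(fit$sd_axes)) - specs$sd[i]) / specs$sd[i], 0.2)
    expect_equal(sign(fit$amplitude), specs$polarity[i])
  }
  ## STA of shuffled spikes is null
  set.seed(76)
  shuf <- runif(length(sim$spike_times[[1]]), 0.6, stim$duration)
  sta_s <- compute_sta(shuf, stim, n_lags = 15)
  expect_lt(max(abs(sta_s$average)), 4.5 / sqrt(sta_s$n_spikes))
})

test_that("LN model degenerate cases follow Poisson statistics", {
  stim <- checkerboard_stimulus(3000, 8, 8, seed = 77)
  specs <- data.frame(x0 = 4, y0 = 4, sd = 1, polarity = 1, gain = 0,
                      baseline = 12)
  sim <- simulate_ln_neurons(specs, stim, seed = 78)
  ## zero gain -> homogeneous Poisson at baseline
  expect_true(all(sim$rates == 12))
  n_sp <- length(sim$spike_times[[1]])
  mu <- 12 * stim$duration
  expect_lt(abs(n_sp - mu), 3 * sqrt(mu))
  ## RF outside the stimulus errors
  bad <- data.frame(x0 = 30, y0 = 4, sd = 1, polarity = 1, gain = 1,
                    baseline = 5)
  expect_error(simulate_ln_neurons(bad, stim), "extent")
})

test_that("mosaic statistics distinguish lattices from random centers", {
  hex <- list()
  for (r in 0:4) for (q in 0:4) {
    hex[[length(hex) + 1]] <- make_rf_fit(2 * q + r, sqrt(3) * r)
  }
  ms <- mosaic_stats(hex)
  expect_lt(ms$nn_cv, 0.1)
  expect_equal(ms$overlap_fraction, 1)  # spacing 2 = 2 sigma -> 1-SD contours touch
  ## Poisson centers at equal density: higher NN-distance CV
  cvs <- vapply(1:10, function(s) {
    set.seed(80 + s)
    rnd <- lapply(seq_len(25), function(i) make_rf_fit(runif(1, 0, 10),
                                                       runif(1, 0, 8)))
    mosaic_stats(rnd, region = c(0, 10, 0, 8))$nn_cv
  }, numeric(1))
  expect_gt(min(cvs), ms$nn_cv + 0.1)
  expect_error(mosaic_stats(hex[1:2]), "at least 3")
  expect_error(mosaic_stats(hex, region = c(0, 0, 0, 5)), "degenerate")
})
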