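test_that("selectivity indices satisfy their closed-form identities", {
  ens <- default_ensemble()
  ## one-direction responder in one grating condition
  r <- array(0, c(1, 6, 8, 25)); r[1, 1, 1, ] <- 5
  m1 <- maps_from_array(r)
  od <- orientation_direction_selectivity(m1)
  expect_equal(od$osi, 1); expect_equal(od$dsi, 1)
  expect_equal(grating_vs_flow_index(m1), 1)
  expect_equal(distributed_selectivity(m1)[[1]], 0)
  ## uniform tuning -> osi = dsi = 0
  r2 <- array(1, c(1, 6, 8, 25))
  od2 <- orientation_direction_selectivity(maps_from_array(r2))
  expect_equal(od2$osi, 0, tolerance = 1e-12)
  expect_equal(od2$dsi, 0, tolerance = 1e-12)
  expect_equal(distributed_selectivity(maps_from_array(r2))[[1]], 1)
  ## cosine tuning 1 + cos(2(theta - theta0)) -> osi 0.5, dsi 0
  th <- (0:7) * pi / 4
  r3 <- array(0, c(1, 6, 8, 25))
  for (d in 1:8) r3[1, 2, d, ] <- 1 + cos(2 * (th[d] - 0.6))
  od3 <- orientation_direction_selectivity(maps_from_array(r3))
  expect_equal(od3$osi, 0.5, tolerance = 1e-12)
  expect_equal(od3$dsi, 0, tolerance = 1e-12)
  ## all-zero -> (0, 0) flagged
  odz <- orientation_direction_selectivity(maps_from_array(array(0, c(1, 6, 8, 25))))
  expect_true(odz$untuned)
  expect_equal(c(odz$osi, odz$dsi), c(0, 0))
})

test_that("grating/flow and polarity indices follow their ratio definitions", {
  mk <- function(cond_rates) {
    r <- array(0, c(1, 6, 8, 25))
    for (ci in 1:6) r[1, ci, , ] <- cond_rates[ci]
    maps_from_array(r)
  }
  ## F = 3 G -> -0.5 (gratings are conditions 1:2; flows 3:6)
  expect_equal(grating_vs_flow_index(mk(c(1, 1, 3, 3, 3, 3))), -0.5)
  expect_equal(grating_vs_flow_index(mk(rep(2, 6))), 0)
  expect_equal(grating_vs_flow_index(mk(rep(0, 6))), 0)
  ## polarity: positive flows are conditions 3, 5; negative 4, 6
  expect_equal(contrast_polarity_index(mk(c(0, 0, 1, 0, 1, 0))), 1)
  expect_equal(contrast_polarity_index(mk(c(0, 0, 1, 2, 1, 2))), -1 / 3)
  expect_equal(contrast_polarity_index(mk(rep(0, 6))), 0)
  ## entropy example: condition means (2, 1, 1, 0, 0, 0)
  H <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25))
  expect_equal(distributed_selectivity(mk(c(2, 1, 1, 0, 0, 0)))[[1]],
               H / log(6))
})

test_that("indices are invariant to rate rescaling and direction shifts", {
  set.seed(61)
  r <- array(runif(2 * 6 * 8 * 25), c(2, 6, 8, 25))
  m <- maps_from_array(r)
  m10 <- maps_from_array(r * 10)
  expect_equal(grating_vs_flow_index(m), grating_vs_flow_index(m10))
  expect_equal(contrast_polarity_index(m), contrast_polarity_index(m10))
  expect_equal(distributed_selectivity(m), distributed_selectivity(m10))
  od <- orientation_direction_selectivity(m)
  ## circular shift of the direction axis
  perm <- c(4:8, 1:3)
  ms <- maps_from_array(r[, , perm, , drop = FALSE])
  ods <- orientation_direction_selectivity(ms)
  expect_equal(ods$osi, od$osi, tolerance = 1e-12)
  expect_equal(ods$dsi, od$dsi, tolerance = 1e-12)
})

test_that("significance calls are calibrated and powered", {
  ## type-I: evoked identical to baseline, 1000 neurons
  m0 <- poisson_maps(1000, matrix(5, 1000, 6), seed = 62)
  sig0 <- response_significance(m0, baseline_rate = 5, alpha = 0.05)
  expect_lte(max(colMeans(sig0)), 0.05)
  ## power: evoked 5x baseline with 20 trials
  m1 <- poisson_maps(400, matrix(25, 400, 6), seed = 63)
  sig1 <- response_significance(m1, baseline_rate = 5, alpha = 0.05)
  expect_gte(mean(sig1), 0.99)
  ## zero spikes everywhere: not significant, no errors
  mz <- poisson_maps(3, matrix(0, 3, 6), seed = 64)
  expect_false(any(response_significance(mz, baseline_rate = 5)))
  ## missing baseline instructs the user
  expect_error(response_significance(m0), "baseline")
  ## normalized maps rejected
  expect_error(response_significance(normalize_maps(m0), 5), "un-normalized")
})

test_that("population fractions recover a constructed 17% sole-low-SF population", {
  set.seed(65)
  n <- 400
  sole <- rbinom(n, 1, 0.17) == 1
  rate <- matrix(5, n, 6)          # baseline-level everywhere
  rate[sole, 1] <- 40              # strong response to low-SF grating only
  rate[!sole, ] <- 40              # responsive to everything
  m <- poisson_maps(n, rate, seed = 66)
  prof <- selectivity_profiles(m, baseline_rate = 5)
  fr <- population_fractions(prof)
  expect_equal(fr$n, n)
  expect_lt(abs(fr$frac_sole_low_sf - mean(sole)),
            2 * sqrt(0.17 * 0.83 / n) + 0.02)
  ## all-identical sole-low-SF population (noise-free rates) -> fraction 1
  r1 <- array(5, c(50, 6, 8, 25)); r1[, 1, , ] <- 60
  p1 <- selectivity_profiles(maps_from_array(r1), baseline_rate = 5)
  expect_equal(population_fractions(p1)$frac_sole_low_sf, 1)
  expect_error(population_fractions(p1[0, ]), "empty")
})
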