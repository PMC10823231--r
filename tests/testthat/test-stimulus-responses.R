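test_that("default ensemble matches the factorial grating/flow design", {
  ens <- default_ensemble()
  expect_length(ens, 6)
  expect_true(all(vapply(ens, function(c) c$n_directions, integer(1)) == 8L))
  expect_true(all(vapply(ens, function(c) c$duration, numeric(1)) == 1.25))
  expect_true(all(vapply(ens, function(c) c$temporal_frequency, numeric(1)) == 4))
  sf <- vapply(ens, function(c) c$spatial_frequency, numeric(1))
  fam <- vapply(ens, function(c) c$family, character(1))
  expect_setequal(sf[fam == "grating"], c(0.04, 0.24))
  pol <- vapply(ens, function(c) {
    p <- c$contrast_polarity
    if (is.na(p)) NA_real_ else p
  }, numeric(1))
  expect_equal(sort(pol[fam != "grating"]), c(-1, -1, 1, 1))
  expect_identical(n_stimulus_slots(ens), 48L)
  for (c in ens) {
    expect_equal(diff(c$direction_angles), rep(45, 7))
  }
})

test_that("bin_psth computes trial-averaged rates and validates input", {
  ens <- structure(list(stimulus_condition("grating_lo", "grating", 0.04,
                                           n_trials = 2)),
                   class = "stimulus_ensemble")
  tab <- data.frame(neuron_id = "n1", condition_id = "grating_lo",
                    direction_deg = 0,
                    trial = c(1, 1, 2, 2), spike_time_s = c(0.10, 0.20, 0.10, 0.20))
  sd1 <- spike_data(tab, ens)
  maps <- bin_psth(sd1, bin_width = 0.25)
  expect_equal(as.numeric(maps$rates[1, 1, 1, ]), c(8, 0, 0, 0, 0))
  expect_true(all(maps$rates[1, 1, -1, ] == 0))
  expect_equal(maps$alignment_shifts, 0L)

  ## empty spikes -> all-zero maps
  empty <- spike_data(tab[0, ], ens, neuron_ids = c("n1", "n2"))
  m0 <- bin_psth(empty, 0.25)
  expect_true(all(m0$rates == 0))
  expect_equal(dim(m0$rates), c(2, 1, 8, 5))

  ## spike outside the trial errors with the neuron named
  bad <- tab; bad$spike_time_s[2] <- 1.7
  expect_error(spike_data(bad, ens), "n1")

  ## invariance to trial order
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(bin_psth(spike_data(perm, ens), 0.25)$rates, maps$rates)

  ## bin width must divide duration
  expect_error(bin_psth(sd1, 0.3), "divide")
})

test_that("bin_psth conserves spike count and recovers a Poisson rate", {
  ens <- structure(list(stimulus_condition("grating_lo", "grating", 0.04,
                                           n_trials = 200)),
                   class = "stimulus_ensemble")
  set.seed(11)
  rows <- list()
  for (d in seq(0, 315, by = 45)) {
    for (tr in 1:200) {
      nsp <- rpois(1, 20 * 1.25)
      if (nsp) rows[[length(rows) + 1]] <- data.frame(
        neuron_id = "n1", condition_id = "grating_lo", direction_deg = d,
        trial = tr, spike_time_s = runif(nsp, 0, 1.25))
    }
  }
  tab <- do.call(rbind, rows)
  maps <- bin_psth(spike_data(tab, ens), 0.25)
  ## conservation: sum(rates) * bin_width * n_trials == total spikes
  expect_equal(sum(maps$rates) * 0.25 * 200, nrow(tab))
  ## every bin within 20 +/- 3 spikes/s (> 4 x SE; SE ~ 0.63 Hz at
  ## 200 trials x 0.25-s bins)
  expect_true(all(abs(maps$rates - 20) < 3))
})

test_that("normalization scales each neuron to unit peak and is idempotent", {
  r <- array(0, c(3, 6, 8, 5))
  r[1, 1, 1, ] <- c(40, 10, 0, 0, 0)
  r[2, 3, 5, 2] <- 7
  maps <- maps_from_array(r, bin_width = 0.25)
  nm <- normalize_maps(maps)
  expect_equal(max(nm$rates[1, , , ]), 1)
  expect_equal(max(nm$rates[2, , , ]), 1)
  expect_true(all(nm$rates[3, , , ] == 0))
  expect_true(nm$silent[3]); expect_false(nm$silent[1])
  expect_equal(normalize_maps(nm)$rates, nm$rates)
})

test_that("direction alignment shifts the peak to index 1 and is invertible", {
  base <- array(0, c(1, 6, 8, 5))
  for (ci in 1:6) base[1, ci, 4, ] <- 1  # peak at direction index 4
  maps <- maps_from_array(base)
  al <- align_directions(maps)
  expect_equal(al$alignment_shifts, 3L)
  en <- apply(al$rates[1, , , ], 2, sum)
  expect_identical(which.max(en), 1L)
  ## identity case
  base0 <- array(0, c(1, 6, 8, 5)); base0[1, , 1, ] <- 1
  expect_equal(align_directions(maps_from_array(base0))$alignment_shifts, 0L)
  ## unalign recovers the original
  expect_equal(unalign_directions(al)$rates, maps$rates)
})

test_that("alignment result is invariant to any prior circular shift", {
  set.seed(3)
  base <- array(runif(6 * 8 * 5), c(1, 6, 8, 5))
  base[1, , 3, ] <- base[1, , 3, ] + 2   # unambiguous peak
  ref <- align_directions(maps_from_array(base))
  for (s in 0:7) {
    perm <- ((seq_len(8) - 1 - s) %% 8) + 1
    shifted <- base[, , perm, , drop = FALSE]
    al <- align_directions(maps_from_array(shifted))
    expect_equal(al$rates, ref$rates, tolerance = 1e-12)
    expect_equal((al$alignment_shifts - ref$alignment_shifts) %% 8, s %% 8)
  }
})

test_that("alignment commutes with normalization", {
  set.seed(4)
  base <- array(runif(2 * 6 * 8 * 5), c(2, 6, 8, 5))
  m <- maps_from_array(base)
  a <- normalize_maps(align_directions(m))
  b <- align_directions(normalize_maps(m))
  expect_equal(a$rates, b$rates)
  expect_equal(a$alignment_shifts, b$alignment_shifts)
})

test_that("the response tensor flattens (condition, direction) with a round-trip index", {
  set.seed(5)
  rates <- array(runif(10 * 6 * 8 * 25), c(10, 6, 8, 25))
  maps <- normalize_maps(maps_from_array(rates))
  tens <- build_tensor(maps)
  expect_equal(dim(tens$values), c(10, 48, 25))
  expect_true(all(tens$values >= 0))
  for (s in seq_len(48)) {
    info <- slot_info(tens, s)
    ci <- match(info$condition_id, condition_ids(maps$ensemble))
    expect_equal(tens$values[, s, ], maps$rates[, ci, info$direction_index, ])
    ## index round-trip: slot of (condition, direction) is s
    expect_equal((ci - 1) * 8 + info$direction_index, s)
  }
})
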