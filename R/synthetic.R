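## Generators for every validation input of the pipeline: the ring
## attractor population, stochastic block models, discrete-type
## ("retina-like"), continuum ("V1-like") and feature-map ("CNN-like")
## populations, and linear-nonlinear model neurons for STA validation.

#' Simulate a ring-attractor population of direction-tuned neurons
#'
#' Threshold-linear recurrent ring network: neuron `i` at angle `theta_i`
#' obeys `tau * dm_i/dt = -m_i + [h_i + (1/N) sum_j (J2 cos(theta_i -
#' theta_j) - J0) m_j]_+`, i.e. uniform inhibition of strength `J0` plus
#' cosine-modulated excitation of strength `J2`, so neurons tuned to
#' nearby directions excite one another and differently tuned neurons
#' inhibit each other. For `J2 > 2` (marginal regime) the network's
#' equilibria form a ring: a bump of activity at the input direction (or
#' at an arbitrary direction when the input is untuned).
#'
#' The population is stimulated with a low spatial-frequency grating
#' drifting in `n_directions` directions; each direction is integrated to
#' equilibrium and the equilibrium profile is combined with one shared
#' saturating temporal kernel, so all neurons have identical response
#' dynamics and differ only in tuning.
#'
#' @param n_neurons Number of neurons (preferred directions uniform on
#'   the circle); `>= 8`.
#' @param J0 Uniform inhibition strength (> 0).
#' @param J2 Modulated excitation strength; `J2 > 2` is the bump-forming
#'   marginal regime.
#' @param tau Membrane time constant, seconds.
#' @param input_strength,input_tuning Input drive `h_i = input_strength *
#'   (1 - input_tuning + input_tuning * cos(theta_i - theta_stim))`;
#'   `input_tuning = 0` is the untuned probe of the marginal regime.
#' @param n_directions Stimulus directions (45 deg spacing for 8).
#' @param n_bins,duration Temporal resolution of the response maps.
#' @param n_trials Trials recorded per direction (metadata; the rate
#'   dynamics are deterministic).
#' @param spikes If `TRUE`, also emit Poisson spikes and return a
#'   [spike_data] object.
#' @param rate_scale Peak firing rate (spikes/s) that the bump maximum is
#'   mapped to.
#' @param seed Seed for the initial condition (and spikes).
#'
#' @return List with `maps` (a [response_maps] over a single low-SF
#'   grating condition), `preferred_deg` (ground-truth preferred
#'   direction per neuron), `equilibria` (`N x n_directions` equilibrium
#'   rates), and `spikes` (if requested).
#' @export
simulate_ring <- function(n_neurons = 64, J0 = 4, J2 = 8, tau = 0.02,
                          input_strength = 2, input_tuning = 0.3,
                          n_directions = 8, n_bins = 25, duration = 1.25,
                          n_trials = 20, spikes = FALSE, rate_scale = 60,
                          seed = 1) {
  if (n_neurons < 8) stop("n_neurons must be >= 8")
  theta <- seq(0, 2 * pi, length.out = n_neurons + 1)[seq_len(n_neurons)]
  J <- (J2 * cos(outer(theta, theta, `-`)) - J0) / n_neurons
  stim_dirs <- seq(0, 360, length.out = n_directions + 1)[seq_len(n_directions)]
  eq <- matrix(0, n_neurons, n_directions)
  dt <- 1e-3
  n_steps <- 600L
  init <- with_seed(seed, 0.01 * stats::runif(n_neurons))
  for (d in seq_len(n_directions)) {
    h <- input_strength *
      (1 - input_tuning + input_tuning * cos(theta - stim_dirs[d] * pi / 180))
    m <- init
    for (s in seq_len(n_steps)) {
      m <- m + dt / tau * (-m + pmax(h + J %*% m, 0))
      if (max(m) > 1e6) {
        stop("ring dynamics diverged: parameters outside the stable regime ",
             "(uniform inhibition J0 too weak for excitation J2)")
      }
    }
    eq[, d] <- m
  }
  if (max(eq) <= 0) stop("ring network silent; increase input_strength")
  eq_rate <- eq / max(eq) * rate_scale
  tb <- (seq_len(n_bins) - 0.5) * duration / n_bins
  gt <- 1 - exp(-tb / (3 * tau))           # shared temporal kernel
  ens <- structure(list(
    stimulus_condition("grating_lo", "grating", 0.04,
                       n_directions = n_directions,
                       duration = duration, n_trials = n_trials)),
    class = "stimulus_ensemble")
  rates <- array(0, dim = c(n_neurons, 1, n_directions, n_bins))
  for (d in seq_len(n_directions)) rates[, 1, d, ] <- outer(eq_rate[, d], gt)
  maps <- new_response_maps(rates, duration / n_bins, ens)
  out <- list(maps = maps,
              preferred_deg = theta * 180 / pi,
              equilibria = eq_rate)
  if (spikes) {
    out$spikes <- rates_to_spikes(maps, seed = seed + 1L)
  }
  out
}

# Emit inhomogeneous-Poisson spikes from trial-averaged rate maps.
rates_to_spikes <- function(maps, seed = 1) {
  ens <- maps$ensemble
  d <- dim(maps$rates)
  bw <- maps$bin_width
  with_seed(seed, {
    rows <- vector("list", 0)
    for (ci in seq_len(d[2])) {
      cond <- ens[[ci]]
      for (di in seq_len(d[3])) {
        lam <- maps$rates[, ci, di, , drop = FALSE] * bw  # N x T expected counts
        lam <- array(lam, dim = c(d[1], d[4]))
        for (tr in seq_len(cond$n_trials)) {
          cnt <- matrix(stats::rpois(length(lam), lam), d[1], d[4])
          nz <- which(cnt > 0, arr.ind = TRUE)
          if (!nrow(nz)) next
          reps <- cnt[nz]
          ni <- rep(nz[, 1], reps)
          bi <- rep(nz[, 2], reps)
          tt <- (bi - 1 + stats::runif(length(bi))) * bw
          rows[[length(rows) + 1L]] <- data.frame(
            neuron_id = sprintf("n%03d", ni),
            condition_id = cond$condition_id,
            direction_deg = cond$direction_angles[di],
            trial = tr, spike_time_s = tt)
        }
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(neuron_id = character(0), condition_id = character(0),
                 direction_deg = numeric(0), trial = integer(0),
                 spike_time_s = numeric(0))
    spike_data(tab, ens, neuron_ids = sprintf("n%03d", seq_len(d[1])))
  })
}

#' Sample a stochastic block model graph
#'
#' Symmetric 0/1 adjacency with independent edges: probability `p_in`
#' within a block, `p_out` between blocks; no self-loops.
#'
#' @param n Nodes.
#' @param K Blocks.
#' @param p_in,p_out Edge probabilities, `0 <= p_out <= p_in <= 1`.
#' @param block_sizes Optional sizes summing to `n`; default near-equal.
#' @param seed RNG seed.
#' @return List with `adjacency` (`n x n`) and `blocks` (labels).
#' @export
generate_sbm <- function(n, K, p_in, p_out, block_sizes = NULL, seed = 1) {
  if (!(p_out <= p_in && p_in <= 1 && p_out >= 0)) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  if (is.null(block_sizes)) {
    block_sizes <- diff(round(seq(0, n, length.out = K + 1)))
  }
  if (sum(block_sizes) != n) stop("block sizes must sum to n")
  blocks <- rep(seq_len(K), times = block_sizes)
  with_seed(seed, {
    P <- ifelse(outer(blocks, blocks, `==`), p_in, p_out)
    U <- matrix(stats::runif(n * n), n, n)
    U[lower.tri(U)] <- t(U)[lower.tri(U)]
    A <- (U < P) * 1
    diag(A) <- 0
    list(adjacency = A, blocks = blocks)
  })
}

## ---- template machinery for population generators -----------------------

von_mises_tuning <- function(n_directions, kappa, pref_index = 1) {
  th <- seq(0, 2 * pi, length.out = n_directions + 1)[seq_len(n_directions)]
  v <- exp(kappa * cos(th - th[pref_index]))
  v / max(v)
}

temporal_motif <- function(n_bins, latency, width, sustained = 0) {
  tb <- seq(0, 1, length.out = n_bins)
  g <- exp(-(tb - latency)^2 / (2 * width^2))
  g <- g + sustained * (tb > latency)
  g / max(g)
}

# The six stock discrete-type templates (C x D x T each), on the default
# 6-condition ensemble: condition amplitudes, direction-tuning sharpness
# and a temporal motif per type. Type 2 reproduces the delayed-to-positive
# -flows motif; type 6 responds only to the low-SF grating.
stock_templates <- function(C = 6, D = 8, Tb = 25) {
  spec <- list(
    list(amp = c(0.9, 0.8, 0.9, 0.9, 0.8, 0.8), kappa = 0.5,
         lat = 0.25, wid = 0.12, sus = 0.4),           # broadly responsive
    list(amp = c(0.7, 0.0, 1.0, 0.6, 1.0, 0.6), kappa = 1,
         lat = 0.30, wid = 0.10, sus = 0, delay_pos = 0.35), # delayed to + flows
    list(amp = c(0.0, 0.0, 0.0, 1.0, 0.0, 1.0), kappa = 1,
         lat = 0.20, wid = 0.08, sus = 0.6),           # negative flows only
    list(amp = c(1.0, 1.0, 0.2, 0.2, 0.2, 0.2), kappa = 2,
         lat = 0.15, wid = 0.06, sus = 0),             # gratings, transient
    list(amp = c(0.5, 0.2, 0.9, 0.9, 0.9, 0.9), kappa = 6,
         lat = 0.40, wid = 0.15, sus = 0.3),           # direction-tuned flows
    list(amp = c(1.0, 0.0, 0.0, 0.0, 0.0, 0.0), kappa = 3,
         lat = 0.30, wid = 0.12, sus = 0.5)            # sole low-SF grating
  )
  pos_conditions <- c(3, 5)   # positive-contrast flows in default ensemble
  lapply(spec[seq_len(min(6, length(spec)))], function(s) {
    tpl <- array(0, dim = c(C, D, Tb))
    tun <- von_mises_tuning(D, s$kappa)
    for (ci in seq_len(C)) {
      lat <- if (!is.null(s$delay_pos) && ci %in% pos_conditions)
        s$lat + s$delay_pos else s$lat
      tpl[ci, , ] <- s$amp[ci] * outer(tun, temporal_motif(Tb, lat, s$wid, s$sus))
    }
    tpl
  })
}

circular_shift_template <- function(tpl, shift) {
  D <- dim(tpl)[2]
  if (shift %% D == 0) return(tpl)
  perm <- ((seq_len(D) - 1L - shift) %% D) + 1L
  tpl[, perm, , drop = FALSE]
}

#' Generate a synthetic population with known encoding structure
#'
#' Three regimes reproducing the qualitative organization the pipeline is
#' meant to distinguish:
#' * `"discrete"` - each neuron instantiates one of `K` distinct
#'   condition x direction x time templates (distinct stimulus
#'   selectivity and temporal motifs, including a type with a delayed
#'   response to positive-contrast flows) plus rectified Gaussian noise:
#'   a population of discrete cell types, as in the retina.
#' * `"continuum"` - templates are interpolated smoothly along
#'   `latent_dim` uniformly sampled latent variables, so selectivity
#'   varies gradually with no type boundaries, as in V1.
#' * `"feature_map"` - `K` templates with disjoint stimulus/time support
#'   (near-zero cross-template correlation) and many neurons per
#'   template: weight-sharing units, as in a convolutional network.
#'
#' Every neuron receives a random preferred direction (circular shift of
#' its template), which [align_directions()] removes downstream.
#'
#' @param regime `"discrete"`, `"continuum"` or `"feature_map"`.
#' @param n_neurons Population size.
#' @param K Number of types / templates (discrete, feature_map).
#' @param latent_dim Latent dimensionality (continuum), 1-3.
#' @param noise_sd SD of the rectified additive noise, in units of the
#'   unit-peak templates.
#' @param ensemble Stimulus ensemble (default [default_ensemble()]).
#' @param n_bins Time bins per trial.
#' @param rate_scale Peak rate in spikes/s mapped to template value 1.
#' @param spikes If `TRUE`, also return Poisson [spike_data].
#' @param seed RNG seed.
#'
#' @return List with `maps` ([response_maps]), `labels` (discrete /
#'   feature_map) or `latents` (continuum), `templates`, `shifts`
#'   (ground-truth preferred-direction indices), and optionally `spikes`.
#' @export
generate_population <- function(regime = c("discrete", "continuum",
                                           "feature_map"),
                                n_neurons = 600, K = 6, latent_dim = 2,
                                noise_sd = 0.1, ensemble = default_ensemble(),
                                n_bins = 25, rate_scale = 40, spikes = FALSE,
                                seed = 1) {
  regime <- match.arg(regime)
  C <- length(ensemble)
  D <- ensemble[[1]]$n_directions
  if (regime != "continuum" && K > n_neurons) stop("K > n_neurons")
  dur <- ensemble[[1]]$duration
  out <- with_seed(seed, {
    rates <- array(0, dim = c(n_neurons, C, D, n_bins))
    shifts <- sample.int(D, n_neurons, replace = TRUE) - 1L
    labels <- NULL; latents <- NULL; templates <- NULL
    if (regime == "discrete") {
      templates <- stock_templates(C, D, n_bins)
      if (K > length(templates)) stop("discrete regime supports K <= 6 types")
      templates <- templates[seq_len(K)]
      labels <- rep_len(seq_len(K), n_neurons)
      for (i in seq_len(n_neurons)) {
        rates[i, , , ] <- circular_shift_template(templates[[labels[i]]],
                                                  shifts[i])
      }
    } else if (regime == "continuum") {
      stopifnot(latent_dim >= 1, latent_dim <= 3)
      anchors <- stock_templates(C, D, n_bins)
      latents <- matrix(stats::runif(n_neurons * latent_dim),
                        n_neurons, latent_dim)
      for (i in seq_len(n_neurons)) {
        u <- latents[i, ]
        w <- switch(latent_dim,
                    c(1 - u[1], u[1]),
                    c((1 - u[1]) * (1 - u[2]), u[1] * (1 - u[2]),
                      (1 - u[1]) * u[2], u[1] * u[2]),
                    c((1 - u[1]) * (1 - u[2]), u[1] * (1 - u[2]),
                      (1 - u[1]) * u[2] * (1 - u[3]), u[1] * u[2] * (1 - u[3]),
                      (1 - u[1]) * u[3], u[1] * u[3]))
        w <- w / sum(w)
        tpl <- 0
        for (j in seq_along(w)) tpl <- tpl + w[j] * anchors[[j]]
        rates[i, , , ] <- circular_shift_template(tpl, shifts[i])
      }
    } else {  # feature_map: disjoint-support templates, uncorrelated
      templates <- vector("list", K)
      slots <- expand.grid(ci = seq_len(C), half = 1:2)
      if (K > nrow(slots)) stop("feature_map regime supports K <= 12")
      pick <- sample.int(nrow(slots), K)
      half_len <- floor(n_bins / 2)
      for (kk in seq_len(K)) {
        tpl <- array(0, dim = c(C, D, n_bins))
        ci <- slots$ci[pick[kk]]
        tb0 <- if (slots$half[pick[kk]] == 1) seq_len(half_len) else
          (half_len + 1):n_bins
        tun <- von_mises_tuning(D, kappa = 2)
        motif <- temporal_motif(length(tb0), 0.5, 0.2)
        tpl[ci, , tb0] <- outer(tun, motif)
        templates[[kk]] <- tpl
      }
      labels <- rep_len(seq_len(K), n_neurons)
      for (i in seq_len(n_neurons)) {
        rates[i, , , ] <- circular_shift_template(templates[[labels[i]]],
                                                  shifts[i])
      }
    }
    if (noise_sd > 0) {
      rates <- pmax(rates + array(stats::rnorm(length(rates), 0, noise_sd),
                                  dim = dim(rates)), 0)
    }
    list(rates = rates, labels = labels, latents = latents,
         templates = templates, shifts = shifts)
  })
  dimnames(out$rates)[[1]] <- sprintf("n%04d", seq_len(n_neurons))
  maps <- new_response_maps(out$rates * rate_scale, dur / n_bins, ensemble)
  res <- list(maps = maps, labels = out$labels, latents = out$latents,
              templates = out$templates, shifts = out$shifts)
  if (spikes) res$spikes <- rates_to_spikes(maps, seed = seed + 1L)
  res
}

#' Simulate linear-nonlinear (LN) model neurons on a checkerboard
#'
#' Forward model for STA validation: each neuron filters the checkerboard
#' through a spatial 2-D Gaussian times a biphasic temporal kernel, passes
#' the drive through a rectifier offset by a baseline rate, and emits
#' inhomogeneous Poisson spikes:
#' `rate(f) = max(0, baseline + gain * sum_lags k(lag) * <G, frame(f - lag)>)`.
#'
#' @param rf_specs Data frame with one row per neuron: columns `x0`, `y0`
#'   (center, square units), `sd` (spatial SD, squares), `polarity` (+1
#'   ON / -1 OFF), `gain` (spikes/s per unit filtered contrast),
#'   `baseline` (spikes/s).
#' @param stimulus A [checkerboard_stimulus()].
#' @param kernel Optional temporal kernel over lags (lag 0 first); default
#'   a biphasic difference of Gaussians over 15 frames, unit L2 norm.
#' @param seed RNG seed.
#' @return List with `spike_times` (list per neuron), `rates` (`neurons x
#'   frames` matrix), `kernel`, and `truth` (the spec table).
#' @export
simulate_ln_neurons <- function(rf_specs, stimulus, kernel = NULL, seed = 1) {
  stopifnot(inherits(stimulus, "checkerboard_stimulus"))
  d <- dim(stimulus$frames)
  nf <- d[1]; nr <- d[2]; nc <- d[3]
  if (any(rf_specs$x0 < 1 | rf_specs$x0 > nc |
          rf_specs$y0 < 1 | rf_specs$y0 > nr)) {
    stop("receptive-field center outside the stimulus extent")
  }
  if (is.null(kernel)) {
    l <- 0:14
    kernel <- exp(-(l - 2)^2 / (2 * 1.2^2)) - 0.6 * exp(-(l - 6)^2 / (2 * 2^2))
    kernel <- kernel / sqrt(sum(kernel^2))
  }
  nl <- length(kernel)
  Fm <- matrix(stimulus$frames, nf, nr * nc)
  fd <- stimulus$frame_duration
  n <- nrow(rf_specs)
  yg <- rep(seq_len(nr), times = nc)
  xg <- rep(seq_len(nc), each = nr)
  with_seed(seed, {
    rates <- matrix(0, n, nf)
    spike_times <- vector("list", n)
    for (i in seq_len(n)) {
      s <- rf_specs[i, ]
      G <- s$polarity * exp(-((xg - s$x0)^2 + (yg - s$y0)^2) / (2 * s$sd^2))
      drive_sp <- as.vector(Fm %*% G)
      drive <- rep(0, nf)
      for (l in seq_len(nl)) {
        drive[l:nf] <- drive[l:nf] + kernel[l] * drive_sp[1:(nf - l + 1)]
      }
      r <- pmax(0, s$baseline + s$gain * drive)
      rates[i, ] <- r
      cnt <- stats::rpois(nf, r * fd)
      nz <- which(cnt > 0)
      if (length(nz)) {
        fi <- rep(nz, cnt[nz])
        spike_times[[i]] <- sort((fi - 1 + stats::runif(length(fi))) * fd)
      } else {
        spike_times[[i]] <- numeric(0)
      }
    }
    list(spike_times = spike_times, rates = rates, kernel = kernel,
         truth = rf_specs)
  })
}
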