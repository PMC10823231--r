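## Per-neuron stimulus-selectivity indices and response-significance calls.
## All indices are ratios of mean evoked rates, so they are invariant to a
## global rescaling of a neuron's firing rate.

condition_families <- function(ensemble) {
  vapply(ensemble, `[[`, character(1), "family")
}

condition_polarity <- function(ensemble) {
  vapply(ensemble, function(c) {
    p <- c$contrast_polarity
    if (is.null(p) || is.na(p)) NA_real_ else as.numeric(p)
  }, numeric(1))
}

low_sf_grating_index <- function(ensemble) {
  fam <- condition_families(ensemble)
  sf <- vapply(ensemble, `[[`, numeric(1), "spatial_frequency")
  gi <- which(fam == "grating")
  if (!length(gi)) stop("ensemble has no grating condition")
  gi[which.min(sf[gi])]
}

#' Mean evoked rate per neuron and condition
#' @param maps A [response_maps] object.
#' @return `N x C` matrix of rates averaged over directions and time.
#' @export
condition_mean_rates <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  apply(maps$rates, c(1, 2), mean)
}

#' Per-condition response significance
#'
#' Calls a neuron responsive to a condition when its total evoked spike
#' count (summed over directions, trials and time) exceeds what the
#' supplied baseline firing rate predicts, by a one-sided exact Poisson
#' test; p-values are Benjamini-Hochberg corrected across the conditions
#' of the ensemble. The test is conservative, so the false-positive rate
#' is at most `alpha` per condition.
#'
#' @param maps *Un-normalized* [response_maps] (rates in spikes/s).
#' @param baseline_rate Baseline firing rate in spikes/s (scalar or
#'   per-neuron vector), e.g. estimated from blank periods.
#' @param alpha Significance level after correction.
#' @param correction Multiple-testing correction across conditions, a
#'   [stats::p.adjust] method.
#'
#' @return `N x C` logical matrix; attribute `"p_values"` carries the
#'   corrected p-values.
#' @export
response_significance <- function(maps, baseline_rate = NULL, alpha = 0.05,
                                  correction = "BH") {
  stopifnot(inherits(maps, "response_maps"))
  if (isTRUE(maps$normalized)) {
    stop("response_significance needs un-normalized rates (spikes/s)")
  }
  if (is.null(baseline_rate)) {
    stop("no baseline available: supply baseline_rate (spikes/s), ",
         "e.g. estimated from blank or pre-stimulus periods")
  }
  ens <- maps$ensemble
  d <- dim(maps$rates)
  n <- d[1]; C <- d[2]; D <- d[3]
  counts <- apply(maps$rates, c(1, 2), sum) * maps$bin_width
  pv <- matrix(NA_real_, n, C, dimnames = list(NULL, condition_ids(ens)))
  for (ci in seq_len(C)) {
    cond <- ens[[ci]]
    tot <- round(counts[, ci] * cond$n_trials)  # total evoked spikes
    mu0 <- baseline_rate * cond$duration * cond$n_trials * D
    pv[, ci] <- stats::ppois(tot - 1, mu0, lower.tail = FALSE)
  }
  padj <- t(apply(pv, 1, stats::p.adjust, method = correction))
  sig <- padj <= alpha
  attr(sig, "p_values") <- padj
  sig
}

#' Grating-versus-flow preference index
#'
#' `(G - F) / (G + F)` with `G` the mean evoked rate over grating
#' conditions and `F` over flow conditions; +1 for pure grating
#' responders, -1 for pure flow responders, 0 when both are zero.
#'
#' @param maps A [response_maps] object.
#' @return Numeric vector in `[-1, 1]`.
#' @export
grating_vs_flow_index <- function(maps) {
  fam <- condition_families(maps$ensemble)
  cm <- condition_mean_rates(maps)
  G <- rowMeans(cm[, fam == "grating", drop = FALSE])
  F_ <- rowMeans(cm[, fam != "grating", drop = FALSE])
  ifelse(G + F_ > 0, (G - F_) / (G + F_), 0)
}

#' Contrast-polarity preference index
#'
#' `(P - N) / (P + N)` over positive- versus negative-contrast flow
#' conditions; 0 when both are zero.
#'
#' @param maps A [response_maps] object.
#' @return Numeric vector in `[-1, 1]`.
#' @export
contrast_polarity_index <- function(maps) {
  pol <- condition_polarity(maps$ensemble)
  if (!any(pol %in% 1) || !any(pol %in% -1)) {
    stop("ensemble lacks flow conditions at both contrast polarities")
  }
  cm <- condition_mean_rates(maps)
  P <- rowMeans(cm[, which(pol %in% 1), drop = FALSE])
  N <- rowMeans(cm[, which(pol %in% -1), drop = FALSE])
  ifelse(P + N > 0, (P - N) / (P + N), 0)
}

#' Orientation and direction selectivity indices (circular variance)
#'
#' From the 8-direction tuning curve of each neuron's best condition
#' (highest mean rate): `dsi = |sum_d r_d e^{i theta_d}| / sum_d r_d` and
#' `osi = |sum_d r_d e^{2 i theta_d}| / sum_d r_d`. Both are invariant to
#' circular shifts of the direction axis. Untuned (all-zero) neurons get
#' `(0, 0)` and are flagged.
#'
#' @param maps A [response_maps] object.
#' @return Data frame with columns `osi`, `dsi`, `best_condition`,
#'   `untuned`.
#' @export
orientation_direction_selectivity <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  cm <- condition_mean_rates(maps)
  best <- apply(cm, 1, which.max)
  d <- dim(maps$rates)
  n <- d[1]
  osi <- dsi <- numeric(n)
  untuned <- logical(n)
  for (i in seq_len(n)) {
    ci <- best[i]
    th <- maps$ensemble[[ci]]$direction_angles * pi / 180
    r <- apply(maps$rates[i, ci, , , drop = FALSE], 3, mean)
    s <- sum(r)
    if (s <= 0) {
      untuned[i] <- TRUE
    } else {
      dsi[i] <- Mod(sum(r * exp(1i * th))) / s
      osi[i] <- Mod(sum(r * exp(2i * th))) / s
    }
  }
  data.frame(osi = osi, dsi = dsi, best_condition = best, untuned = untuned)
}

#' Distributed stimulus selectivity
#'
#' Normalized entropy of the per-condition mean rates, `H / log(C)`: 0 for
#' a one-condition responder, 1 for uniform responses across all
#' conditions, 0 (flagged) for silent neurons.
#'
#' @param maps A [response_maps] object.
#' @return Numeric vector in `[0, 1]`; attribute `"silent"` flags
#'   all-zero neurons.
#' @export
distributed_selectivity <- function(maps) {
  cm <- condition_mean_rates(maps)
  C <- ncol(cm)
  tot <- rowSums(cm)
  silent <- tot <= 0
  p <- cm / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  out <- ifelse(silent, 0, h / log(C))
  attr(out, "silent") <- silent
  out
}

#' Per-neuron selectivity profiles
#'
#' Combines the significance calls and all selectivity indices into one
#' per-neuron table, including the `sole_low_sf_grating` flag (the low
#' spatial-frequency grating is the only condition with a significant
#' response).
#'
#' @param maps Un-normalized [response_maps].
#' @param baseline_rate,alpha Passed to [response_significance()].
#' @return Data frame, one row per neuron, with columns `sig_<condition>`,
#'   `grating_index`, `contrast_polarity_index`, `osi`, `dsi`,
#'   `distributed_index`, `sole_low_sf_grating`, `low_sf_responsive`.
#' @export
selectivity_profiles <- function(maps, baseline_rate, alpha = 0.05) {
  sig <- response_significance(maps, baseline_rate, alpha)
  od <- orientation_direction_selectivity(maps)
  lo <- low_sf_grating_index(maps$ensemble)
  out <- data.frame(
    grating_index = grating_vs_flow_index(maps),
    contrast_polarity_index = contrast_polarity_index(maps),
    osi = od$osi, dsi = od$dsi,
    distributed_index = as.numeric(distributed_selectivity(maps)),
    low_sf_responsive = sig[, lo],
    sole_low_sf_grating = sig[, lo] & rowSums(sig) == 1
  )
  sigdf <- as.data.frame(sig)
  names(sigdf) <- paste0("sig_", colnames(sig))
  cbind(sigdf, out)
}

#' Population fractions of grating-driven neurons
#'
#' Reports (a) the fraction of neurons responsive to the low
#' spatial-frequency grating *and* orientation-tuned (`osi >=
#' osi_threshold`), and (b) the fraction for which the low-SF grating is
#' the sole significant condition.
#'
#' @param profiles Output of [selectivity_profiles()].
#' @param osi_threshold OSI cut for "orientation-tuned"; default 0.5.
#' @return List with `n`, `frac_low_sf_tuned`, `n_low_sf_tuned`,
#'   `frac_sole_low_sf`, `n_sole_low_sf`.
#' @export
population_fractions <- function(profiles, osi_threshold = 0.5) {
  n <- nrow(profiles)
  if (is.null(n) || n == 0) stop("empty population")
  a <- profiles$low_sf_responsive & profiles$osi >= osi_threshold
  b <- profiles$sole_low_sf_grating
  list(n = n,
       frac_low_sf_tuned = mean(a), n_low_sf_tuned = sum(a),
       frac_sole_low_sf = mean(b), n_sole_low_sf = sum(b))
}
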