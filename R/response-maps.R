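#' Trial-averaged response maps
#'
#' A `response_maps` object holds the PSTHs of every neuron under every
#' (condition, direction) pair as a 4-way nonnegative array
#' `neurons x conditions x directions x time_bins`, the "sextet" view of a
#' population: per neuron and condition, rows are motion directions and
#' columns time bins.
#'
#' All conditions must share the same direction count, duration and trial
#' count for the factorial array to be well formed (true of
#' [default_ensemble()]).
#'
#' @name response_maps
NULL

new_response_maps <- function(rates, bin_width, ensemble,
                              normalized = FALSE,
                              alignment_shifts = NULL,
                              silent = NULL) {
  stopifnot(length(dim(rates)) == 4)
  n <- dim(rates)[1]
  if (is.null(alignment_shifts)) alignment_shifts <- integer(n)
  if (is.null(silent)) silent <- logical(n)
  structure(list(rates = rates, bin_width = bin_width, ensemble = ensemble,
                 normalized = normalized,
                 alignment_shifts = as.integer(alignment_shifts),
                 silent = silent),
            class = "response_maps")
}

#' @export
print.response_maps <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf(
    "Response maps: %d neurons x %d conditions x %d directions x %d bins (%.0f ms)%s\n",
    d[1], d[2], d[3], d[4], 1000 * x$bin_width,
    if (x$normalized) ", normalized" else ""))
  if (any(x$alignment_shifts != 0L)) cat("  direction-aligned\n")
  invisible(x)
}

#' Bin spike trains into trial-averaged response maps (PSTHs)
#'
#' Counts spikes in fixed time bins and averages across trials:
#' `rate(n, c, d, b) = spikes in bin b / (n_trials * bin_width)`, in
#' spikes/s.
#'
#' @param spikes A [spike_data] object.
#' @param bin_width Bin width in seconds; must divide the trial duration.
#'
#' @return A [response_maps] object (un-normalized, unshifted).
#' @export
bin_psth <- function(spikes, bin_width = 0.05) {
  stopifnot(inherits(spikes, "spike_data"))
  ens <- spikes$ensemble
  durs <- vapply(ens, `[[`, numeric(1), "duration")
  ndir <- vapply(ens, `[[`, integer(1), "n_directions")
  if (length(unique(durs)) != 1L || length(unique(ndir)) != 1L) {
    stop("conditions differ in duration or direction count; ",
         "a factorial response array requires matched conditions")
  }
  duration <- durs[1]
  nb <- duration / bin_width
  if (abs(nb - round(nb)) > 1e-8) {
    stop(sprintf("bin_width %.4g s does not divide duration %.4g s",
                 bin_width, duration))
  }
  nb <- as.integer(round(nb))
  nid <- spikes$neuron_ids
  n <- length(nid)
  C <- length(ens)
  D <- ndir[1]
  rates <- array(0, dim = c(n, C, D, nb),
                 dimnames = list(nid, condition_ids(ens), NULL, NULL))
  tab <- spikes$spikes
  if (nrow(tab)) {
    ni <- match(tab$neuron_id, nid)
    if (anyNA(ni)) {
      stop("spike table references neuron(s) missing from neuron_ids: ",
           tab$neuron_id[which(is.na(ni))[1]])
    }
    for (ci in seq_len(C)) {
      cond <- ens[[ci]]
      sel <- tab$condition_id == cond$condition_id
      if (!any(sel)) next
      di <- match(tab$direction_deg[sel], cond$direction_angles)
      bi <- pmin(nb, floor(tab$spike_time_s[sel] / bin_width) + 1L)
      idx <- ni[sel] + n * (di - 1L) + n * D * (bi - 1L)
      counts <- tabulate(idx, nbins = n * D * nb)
      rates[, ci, , ] <- array(counts, dim = c(n, D, nb)) /
        (cond$n_trials * bin_width)
    }
  }
  new_response_maps(rates, bin_width, ens)
}

#' Normalize response maps per neuron
#'
#' Divides each neuron's maps by that neuron's global maximum rate, so all
#' neurons live on a common `[0, 1]` scale before factorization while the
#' nonnegativity needed by the NTF is preserved. Silent (all-zero) neurons
#' are left at zero and flagged in `$silent`. Idempotent.
#'
#' @param maps A [response_maps] object.
#' @return A normalized [response_maps] object.
#' @export
normalize_maps <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  mx <- apply(maps$rates, 1, max)
  silent <- mx <= 0
  scale <- ifelse(silent, 1, mx)
  maps$rates <- maps$rates / scale
  maps$normalized <- TRUE
  maps$silent <- silent
  maps
}

direction_energy <- function(maps) {
  # neurons x directions summed response, pooled over conditions and time
  apply(maps$rates, c(1, 3), sum)
}

#' Align each neuron's direction axis to its preferred direction
#'
#' Applies one circular shift per neuron, shared across conditions, that
#' places the direction of maximal summed response at index 1. This factors
#' out direction preference before tensor factorization, so neurons are
#' compared by tuning *shape* and dynamics rather than absolute preferred
#' direction. The shift is recorded in `alignment_shifts` (ties broken by
#' the lowest direction index), making the operation invertible.
#'
#' @param maps A [response_maps] object.
#' @return A [response_maps] object with the direction axis aligned.
#' @export
align_directions <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  D <- dim(maps$rates)[3]
  if (D < 1) stop("need at least one direction")
  en <- direction_energy(maps)
  peak <- apply(en, 1, which.max)  # which.max takes the first (lowest) max
  shift <- peak - 1L
  out <- maps$rates
  for (s in unique(shift)) {
    if (s == 0L) next
    rows <- which(shift == s)
    perm <- ((seq_len(D) - 1L + s) %% D) + 1L
    out[rows, , , ] <- maps$rates[rows, , perm, , drop = FALSE]
  }
  maps$rates <- out
  maps$alignment_shifts <- (maps$alignment_shifts + as.integer(shift)) %% D
  maps
}

#' Undo the direction alignment of [align_directions()]
#' @param maps An aligned [response_maps] object.
#' @return The maps with the original direction axis restored.
#' @export
unalign_directions <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  D <- dim(maps$rates)[3]
  shift <- maps$alignment_shifts
  out <- maps$rates
  for (s in unique(shift)) {
    if (s == 0L) next
    rows <- which(shift == s)
    perm <- ((seq_len(D) - 1L - s) %% D) + 1L
    out[rows, , , ] <- maps$rates[rows, , perm, , drop = FALSE]
  }
  maps$rates <- out
  maps$alignment_shifts <- integer(dim(out)[1])
  maps
}

#' Assemble the neurons x stimuli x time response tensor
#'
#' Flattens the (condition, direction) axes of a set of response maps into
#' a single stimulus axis of `S = conditions * directions` slots, giving the
#' 3-way nonnegative tensor factorized by [ntf_decompose()]. `index_map`
#' round-trips every slot to its (condition, direction) pair.
#'
#' @param maps A [response_maps] object (typically normalized, and aligned
#'   when direction preference is to be factored out).
#' @return An object of class `response_tensor` with fields `values`
#'   (`N x S x T` array), `index_map` (data.frame `slot`, `condition_id`,
#'   `direction_index`, `direction_deg`), `bin_width`, `ensemble`.
#' @export
build_tensor <- function(maps) {
  stopifnot(inherits(maps, "response_maps"))
  d <- dim(maps$rates)
  n <- d[1]; C <- d[2]; D <- d[3]; Tb <- d[4]
  vals <- array(0, dim = c(n, C * D, Tb),
                dimnames = list(dimnames(maps$rates)[[1]], NULL, NULL))
  cid <- condition_ids(maps$ensemble)
  idx <- data.frame(slot = seq_len(C * D),
                    condition_id = rep(cid, each = D),
                    direction_index = rep(seq_len(D), times = C),
                    direction_deg = unlist(lapply(maps$ensemble,
                                                  `[[`, "direction_angles")))
  for (ci in seq_len(C)) {
    vals[, (ci - 1L) * D + seq_len(D), ] <- maps$rates[, ci, , ]
  }
  structure(list(values = vals, index_map = idx, bin_width = maps$bin_width,
                 ensemble = maps$ensemble,
                 alignment_shifts = maps$alignment_shifts),
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Response tensor: %d neurons x %d stimuli x %d time bins\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Map a stimulus slot back to its (condition, direction)
#' @param tensor A `response_tensor`.
#' @param slot Slot index (1-based).
#' @return One-row data.frame from the tensor's index map.
#' @export
slot_info <- function(tensor, slot) {
  stopifnot(inherits(tensor, "response_tensor"))
  tensor$index_map[slot, , drop = FALSE]
}
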