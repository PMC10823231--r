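#' Spike-train container
#'
#' Holds the spike times of a recorded (or simulated) population under a
#' stimulus ensemble, in long format: one row per spike with the neuron,
#' condition, direction and trial it belongs to. Trials with no spikes need
#' no rows; `neuron_ids` fixes the full roster so silent neurons are kept.
#'
#' @param spikes `data.frame` with columns `neuron_id`, `condition_id`,
#'   `direction_deg`, `trial`, `spike_time_s`. May have zero rows.
#' @param ensemble A [stimulus_ensemble][default_ensemble] describing the
#'   conditions referenced by `condition_id`.
#' @param neuron_ids Character vector of all neurons (default: those present
#'   in `spikes`).
#' @param metadata Optional per-neuron `data.frame` with a `neuron_id`
#'   column (area, layer, putative type, ...).
#'
#' @return Object of class `spike_data`.
#' @export
spike_data <- function(spikes, ensemble, neuron_ids = NULL, metadata = NULL) {
  required <- c("neuron_id", "condition_id", "direction_deg", "trial",
                "spike_time_s")
  missing <- setdiff(required, names(spikes))
  if (length(missing)) {
    stop("spike table is missing column(s): ", paste(missing, collapse = ", "))
  }
  spikes$neuron_id <- as.character(spikes$neuron_id)
  spikes$condition_id <- as.character(spikes$condition_id)
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  cids <- condition_ids(ensemble)
  bad <- setdiff(unique(spikes$condition_id), cids)
  if (length(bad)) {
    stop("unknown condition_id(s) in spike table: ", paste(bad, collapse = ", "))
  }
  for (cond in ensemble) {
    sel <- spikes$condition_id == cond$condition_id
    if (!any(sel)) next
    tt <- spikes$spike_time_s[sel]
    if (anyNA(tt) || any(tt < 0) || any(tt > cond$duration)) {
      off <- which(sel)[which(is.na(tt) | tt < 0 | tt > cond$duration)[1]]
      stop(sprintf(
        "spike time %.4f s outside [0, %.3f] for neuron %s, condition %s, trial %d",
        spikes$spike_time_s[off], cond$duration, spikes$neuron_id[off],
        cond$condition_id, spikes$trial[off]))
    }
    dirs <- unique(spikes$direction_deg[sel])
    badd <- setdiff(dirs, cond$direction_angles)
    if (length(badd)) {
      stop(sprintf("direction %g deg not part of condition %s",
                   badd[1], cond$condition_id))
    }
  }
  if (!is.null(metadata)) {
    if (!"neuron_id" %in% names(metadata)) stop("metadata needs a neuron_id column")
    metadata$neuron_id <- as.character(metadata$neuron_id)
  }
  structure(list(spikes = spikes, ensemble = ensemble,
                 neuron_ids = as.character(neuron_ids), metadata = metadata),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat("Spike data:", length(x$neuron_ids), "neurons,",
      nrow(x$spikes), "spikes,", length(x$ensemble), "conditions\n")
  invisible(x)
}

#' Read and write spike tables (long-format CSV)
#'
#' The on-disk dialect is a plain CSV with columns `neuron_id`,
#' `condition_id`, `direction_deg`, `trial`, `spike_time_s`.
#' `read_spikes(write_spikes(x))` round-trips.
#'
#' @param x A [spike_data] object.
#' @param path CSV file path.
#' @param ensemble Ensemble descriptor for validation on read.
#' @param ... Passed to [spike_data()] on read (`neuron_ids`, `metadata`).
#' @return `read_spikes` returns a `spike_data`; `write_spikes` the path,
#'   invisibly.
#' @export
write_spikes <- function(x, path) {
  stopifnot(inherits(x, "spike_data"))
  utils::write.csv(x$spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, ensemble, ...) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  if (nrow(tab) == 0 && ncol(tab) == 0) stop("empty spike file: ", path)
  numcols <- c("direction_deg", "trial", "spike_time_s")
  for (cn in intersect(numcols, names(tab))) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v)) {
        stop(sprintf("column %s of %s is not numeric (first bad row %d)",
                     cn, path, which(is.na(v2))[1]))
      }
      tab[[cn]] <- v2
    }
  }
  spike_data(tab, ensemble, ...)
}
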