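#' Stimulus condition descriptor
#'
#' A stimulus condition is one entry of the factorial ensemble: a drifting
#' grating or flow pattern presented in `n_directions` equally spaced
#' directions of motion for `n_trials` repeats of `duration` seconds each.
#'
#' @param condition_id Short label, e.g. `"grating_lo"`.
#' @param family One of `"grating"`, `"dot-flow"`, `"line-flow"`.
#' @param spatial_frequency Dominant spatial frequency, cycles/degree.
#' @param contrast_polarity `+1` (bright elements), `-1` (dark elements) or
#'   `NA` for gratings, whose contrast is symmetric.
#' @param temporal_frequency Drift rate, cycles/second.
#' @param n_directions Number of motion directions.
#' @param direction_angles Direction angles in degrees; must be equally
#'   spaced over `[0, 360)`. Defaults to `n_directions` angles from 0.
#' @param duration Trial duration, seconds.
#' @param n_trials Number of repeats.
#'
#' @return An object of class `stimulus_condition` (a named list).
#' @export
stimulus_condition <- function(condition_id, family,
                               spatial_frequency,
                               contrast_polarity = NA_real_,
                               temporal_frequency = 4,
                               n_directions = 8,
                               direction_angles = NULL,
                               duration = 1.25,
                               n_trials = 20) {
  family <- match.arg(family, c("grating", "dot-flow", "line-flow"))
  if (is.null(direction_angles)) {
    direction_angles <- seq(0, 360, length.out = n_directions + 1L)[seq_len(n_directions)]
  }
  stopifnot(length(direction_angles) == n_directions)
  if (n_directions > 1L) {
    gaps <- diff(c(direction_angles, direction_angles[1] + 360))
    if (max(abs(gaps - 360 / n_directions)) > 1e-9) {
      stop("direction_angles must be equally spaced over [0, 360)")
    }
  }
  if (duration <= 0) stop("duration must be > 0")
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(
    condition_id = as.character(condition_id),
    family = family,
    spatial_frequency = spatial_frequency,
    contrast_polarity = contrast_polarity,
    temporal_frequency = temporal_frequency,
    n_directions = as.integer(n_directions),
    direction_angles = as.numeric(direction_angles),
    duration = duration,
    n_trials = as.integer(n_trials)
  ), class = "stimulus_condition")
}

#' Default six-condition stimulus ensemble
#'
#' The ensemble used throughout: a low (0.04 cpd) and a high (0.24 cpd)
#' spatial-frequency drifting grating, single-dot flows at positive and
#' negative contrast, and 3-dot line flows at positive and negative
#' contrast. Every condition drifts in 8 directions separated by 45 deg at
#' 4 cycles/s, with 1.25-s trials.
#'
#' @param n_trials Repeats per (condition, direction); default 20.
#' @param duration Trial duration in seconds; default 1.25.
#'
#' @return A list of 6 [stimulus_condition()] objects, class
#'   `stimulus_ensemble`.
#' @export
#'
#' @examples
#' ens <- default_ensemble()
#' length(ens)            # 6 conditions
#' n_stimulus_slots(ens)  # 48 (condition, direction) pairs
default_ensemble <- function(n_trials = 20, duration = 1.25) {
  conds <- list(
    stimulus_condition("grating_lo", "grating", 0.04,
                       duration = duration, n_trials = n_trials),
    stimulus_condition("grating_hi", "grating", 0.24,
                       duration = duration, n_trials = n_trials),
    stimulus_condition("dotflow_pos", "dot-flow", 0.24, contrast_polarity = +1,
                       duration = duration, n_trials = n_trials),
    stimulus_condition("dotflow_neg", "dot-flow", 0.24, contrast_polarity = -1,
                       duration = duration, n_trials = n_trials),
    stimulus_condition("lineflow_pos", "line-flow", 0.24, contrast_polarity = +1,
                       duration = duration, n_trials = n_trials),
    stimulus_condition("lineflow_neg", "line-flow", 0.24, contrast_polarity = -1,
                       duration = duration, n_trials = n_trials)
  )
  structure(conds, class = "stimulus_ensemble")
}

#' Total number of (condition, direction) stimulus slots in an ensemble
#' @param ensemble A `stimulus_ensemble`.
#' @return Integer count.
#' @export
n_stimulus_slots <- function(ensemble) {
  sum(vapply(ensemble, function(c) c$n_directions, integer(1)))
}

condition_ids <- function(ensemble) {
  vapply(ensemble, function(c) c$condition_id, character(1))
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat("Stimulus ensemble:", length(x), "conditions,",
      n_stimulus_slots(x), "stimulus slots\n")
  for (c in x) {
    cat(sprintf("  %-13s %-9s %.2f cpd, %s, %d dirs, %.2f s x %d trials\n",
                c$condition_id, c$family, c$spatial_frequency,
                if (is.na(c$contrast_polarity)) "contrast +/-"
                else sprintf("contrast %+d", c$contrast_polarity),
                c$n_directions, c$duration, c$n_trials))
  }
  invisible(x)
}

ensemble_to_list <- function(ensemble) {
  lapply(ensemble, function(c) unclass(c))
}

ensemble_from_list <- function(lst) {
  structure(lapply(lst, function(c) {
    do.call(stimulus_condition, c[c("condition_id", "family",
                                    "spatial_frequency", "contrast_polarity",
                                    "temporal_frequency", "n_directions",
                                    "direction_angles", "duration",
                                    "n_trials")])
  }), class = "stimulus_ensemble")
}

#' Read / write a stimulus ensemble descriptor (YAML or JSON)
#'
#' @param ensemble A `stimulus_ensemble`.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_ensemble` returns a `stimulus_ensemble`;
#'   `write_ensemble` returns `path` invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  lst <- ensemble_to_list(ensemble)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  lst <- lapply(lst, function(c) {
    c$direction_angles <- as.numeric(unlist(c$direction_angles))
    p <- c$contrast_polarity
    c$contrast_polarity <- if (is.null(p) || is.na(p)) NA_real_
    else as.numeric(p)
    c
  })
  ensemble_from_list(lst)
}
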