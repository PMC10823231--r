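#' Binary checkerboard noise stimulus
#'
#' White-noise checkerboard used for spike-triggered-average receptive
#' field estimation: each frame assigns every square an independent
#' contrast of -1 or +1; a new frame is shown every `frame_duration`
#' seconds (33 ms by default).
#'
#' @param n_frames Number of frames.
#' @param n_rows,n_cols Checker grid size.
#' @param frame_duration Seconds per frame.
#' @param square_size Side of one square, in spatial units (used only as
#'   metadata for reporting fits in physical units).
#' @param seed RNG seed.
#' @return Object of class `checkerboard_stimulus`: `frames`
#'   (`time x rows x cols` array of +/-1), `frame_duration`,
#'   `square_size`, `mean_value` (0), `duration`.
#' @export
checkerboard_stimulus <- function(n_frames, n_rows = 16, n_cols = 16,
                                  frame_duration = 1 / 30, square_size = 1,
                                  seed = 1) {
  if (frame_duration <= 0) stop("frame_duration must be > 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  frames <- array(sample(c(-1, 1), n_frames * n_rows * n_cols, replace = TRUE),
                  dim = c(n_frames, n_rows, n_cols))
  structure(list(frames = frames, frame_duration = frame_duration,
                 square_size = square_size, mean_value = 0,
                 duration = n_frames * frame_duration),
            class = "checkerboard_stimulus")
}

#' Spike-triggered average of a checkerboard stimulus
#'
#' Averages the `n_lags` frames preceding each spike (lag 0 = the frame on
#' screen at spike time), mean-subtracted; the classical linear
#' receptive-field estimate. Spikes earlier than `n_lags` frames into the
#' stimulus are discarded.
#'
#' @param spike_times Numeric vector of spike times (seconds) within the
#'   stimulus span.
#' @param stimulus A [checkerboard_stimulus()].
#' @param n_lags Number of frames of history; default 15 (about 500 ms at
#'   33-ms frames).
#' @return Object of class `sta`: `average` (`n_lags x rows x cols`, lag 0
#'   first), `n_spikes`, `frame_duration`, `peak_lag`, `spatial` (frame at
#'   the peak lag), `temporal` (time course at the peak pixel).
#' @export
compute_sta <- function(spike_times, stimulus, n_lags = 15) {
  stopifnot(inherits(stimulus, "checkerboard_stimulus"), n_lags >= 1)
  fd <- stimulus$frame_duration
  nf <- dim(stimulus$frames)[1]
  if (any(spike_times < 0 | spike_times > stimulus$duration)) {
    stop("spike time(s) outside the stimulus span")
  }
  fidx <- pmin(nf, floor(spike_times / fd) + 1L)
  fidx <- fidx[fidx >= n_lags]
  if (!length(fidx)) stop("no spikes available for the STA (zero usable spikes)")
  counts <- tabulate(fidx, nbins = nf)
  d <- dim(stimulus$frames)
  Fm <- matrix(stimulus$frames, nf, d[2] * d[3])
  nsp <- length(fidx)
  avg <- matrix(0, n_lags, d[2] * d[3])
  for (lag in 0:(n_lags - 1L)) {
    cs <- c(counts[(1L + lag):nf], rep(0, lag))
    avg[lag + 1L, ] <- crossprod(Fm, cs) / nsp
  }
  avg <- avg - stimulus$mean_value
  A <- array(avg, dim = c(n_lags, d[2], d[3]))
  peak <- which(abs(A) == max(abs(A)), arr.ind = TRUE)[1, ]
  structure(list(average = A, n_spikes = nsp, frame_duration = fd,
                 peak_lag = unname(peak[1]) - 1L,
                 spatial = A[peak[1], , ],
                 temporal = A[, peak[2], peak[3]]),
            class = "sta")
}

#' @export
print.sta <- function(x, ...) {
  d <- dim(x$average)
  cat(sprintf("STA: %d lags x %d x %d squares, %d spikes, peak lag %d\n",
              d[1], d[2], d[3], x$n_spikes, x$peak_lag))
  invisible(x)
}

gauss2d <- function(x, y, x0, y0, sx, sy, theta, A, b) {
  ct <- cos(theta); st <- sin(theta)
  u <- (x - x0) * ct + (y - y0) * st
  v <- -(x - x0) * st + (y - y0) * ct
  A * exp(-u^2 / (2 * sx^2) - v^2 / (2 * sy^2)) + b
}

#' Fit an elliptical 2-D Gaussian to a spatial receptive field
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of
#' `A * exp(-u^2/(2 sx^2) - v^2/(2 sy^2)) + b` in rotated coordinates, to
#' the spatial STA frame. Initialization comes from the centroid and
#' second moments of the thresholded `|frame|`; the amplitude sign (ON vs
#' OFF polarity) comes from the dominant peak.
#'
#' @param frame Numeric matrix (rows = y, cols = x), typically
#'   `sta$spatial`.
#' @return Object of class `rf_fit`: `center` (x, y in square units),
#'   `sd_axes` (`sd_major >= sd_minor`), `orientation` (radians in
#'   `[0, pi)`), `amplitude` (signed), `offset`, `fit_residual` (residual
#'   sum of squares), `converged`.
#' @export
fit_gaussian_rf <- function(frame) {
  frame <- as.matrix(frame)
  if (max(frame) - min(frame) <= .Machine$double.eps * 10 ||
      max(abs(frame)) == 0) {
    stop("flat frame: no dominant peak to fit")
  }
  nr <- nrow(frame); nc <- ncol(frame)
  y <- rep(seq_len(nr), times = nc)
  x <- rep(seq_len(nc), each = nr)
  z <- as.vector(frame)
  pol <- sign(frame[which.max(abs(frame))])
  w <- pmax(pol * z, 0)
  w2 <- ifelse(w >= 0.5 * max(w), w, 0)   # threshold at half peak
  x0 <- sum(x * w2) / sum(w2)
  y0 <- sum(y * w2) / sum(w2)
  sx <- sqrt(sum(w2 * (x - x0)^2) / sum(w2)) + 0.3
  sy <- sqrt(sum(w2 * (y - y0)^2) / sum(w2)) + 0.3
  start <- list(x0 = x0, y0 = y0, sx = sx, sy = sy, theta = 0,
                A = pol * max(abs(frame)), b = 0)
  df <- data.frame(x = x, y = y, z = z)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ gauss2d(x, y, x0, y0, sx, sy, theta, A, b),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed: ", conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  sda <- abs(c(p$sx, p$sy))
  th <- p$theta
  if (sda[2] > sda[1]) {               # ensure major axis first
    sda <- rev(sda)
    th <- th + pi / 2
  }
  th <- th %% pi
  structure(list(center = c(x = p$x0, y = p$y0),
                 sd_axes = c(major = sda[1], minor = sda[2]),
                 orientation = th, amplitude = p$A, offset = p$b,
                 fit_residual = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf(
    "RF fit: center (%.2f, %.2f), SD %.2f x %.2f, orientation %.0f deg, %s\n",
    x$center[1], x$center[2], x$sd_axes[1], x$sd_axes[2],
    x$orientation * 180 / pi, if (x$amplitude >= 0) "ON" else "OFF"))
  invisible(x)
}

#' Mosaic statistics for a set of receptive-field fits
#'
#' Summarizes how a putative cell type tiles space: coverage factor
#' (summed 1-SD ellipse area over the region area), nearest-neighbor
#' center distances (mean, CV, and mean normalized by the mean RF
#' diameter), and the fraction of cells whose 1-SD outline overlaps its
#' nearest neighbor's (using the effective circular radius
#' `sqrt(sd_major * sd_minor)`). A regular mosaic has a low
#' nearest-neighbor CV; random (Poisson) centers have a high one.
#'
#' @param fits List of [rf_fit][fit_gaussian_rf] objects (>= 3).
#' @param region Optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the fitted centers.
#' @return List with `n`, `coverage_factor`, `nn_mean`, `nn_cv`,
#'   `nn_over_diameter`, `overlap_fraction`.
#' @export
mosaic_stats <- function(fits, region = NULL) {
  if (length(fits) < 3) stop("need at least 3 receptive-field fits")
  ctr <- t(vapply(fits, function(f) f$center, numeric(2)))
  sds <- t(vapply(fits, function(f) f$sd_axes, numeric(2)))
  if (is.null(region)) {
    region <- c(min(ctr[, 1]), max(ctr[, 1]), min(ctr[, 2]), max(ctr[, 2]))
  }
  area <- (region[2] - region[1]) * (region[4] - region[3])
  if (!is.finite(area) || area <= 0) {
    stop("degenerate region: zero area")
  }
  Dm <- as.matrix(stats::dist(ctr))
  diag(Dm) <- Inf
  nn_d <- apply(Dm, 1, min)
  nn_i <- apply(Dm, 1, which.min)
  r_eff <- sqrt(sds[, 1] * sds[, 2])
  list(n = length(fits),
       coverage_factor = sum(pi * sds[, 1] * sds[, 2]) / area,
       nn_mean = mean(nn_d),
       nn_cv = stats::sd(nn_d) / mean(nn_d),
       nn_over_diameter = mean(nn_d) / mean(2 * r_eff),
       overlap_fraction = mean(nn_d < r_eff + r_eff[nn_i]))
}
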