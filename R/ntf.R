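#' @keywords internal
#' Mode-n unfolding of a 3-way array, paired with khatri_rao() so that
#' X_(1) = A (C kr B)', X_(2) = B (C kr A)', X_(3) = C (B kr A)'.
unfold3 <- function(X, mode) {
  d <- dim(X)
  switch(mode,
         `1` = matrix(X, d[1], d[2] * d[3]),
         `2` = matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3]),
         `3` = matrix(aperm(X, c(3, 1, 2)), d[3], d[1] * d[2]))
}

khatri_rao <- function(U, V) {
  # column-wise Kronecker product: (nrow(U)*nrow(V)) x R
  nu <- nrow(U); nv <- nrow(V)
  U[rep(seq_len(nu), each = nv), , drop = FALSE] *
    V[rep(seq_len(nv), times = nu), , drop = FALSE]
}

cp_reconstruct <- function(A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  array(A %*% t(khatri_rao(C, B)), dim = d)
}

# One HALS fit from a given nonnegative initialization.
hals_fit <- function(X1, X2, X3, A, B, C, normX2,
                     max_iter = 500, tol = 1e-8) {
  R <- ncol(A)
  rel_err <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## mode 1
    G <- crossprod(B) * crossprod(C)
    M <- X1 %*% khatri_rao(C, B)
    for (r in seq_len(R)) {
      A[, r] <- pmax(0, A[, r] + (M[, r] - A %*% G[, r]) / max(G[r, r], 1e-12))
    }
    ## mode 2
    G <- crossprod(A) * crossprod(C)
    M <- X2 %*% khatri_rao(C, A)
    for (r in seq_len(R)) {
      B[, r] <- pmax(0, B[, r] + (M[, r] - B %*% G[, r]) / max(G[r, r], 1e-12))
    }
    ## mode 3
    GA <- crossprod(A); GB <- crossprod(B)
    G <- GA * GB
    M <- X3 %*% khatri_rao(B, A)
    for (r in seq_len(R)) {
      C[, r] <- pmax(0, C[, r] + (M[, r] - C %*% G[, r]) / max(G[r, r], 1e-12))
    }
    err2 <- normX2 - 2 * sum(C * M) + sum(crossprod(C) * G)
    new_rel <- sqrt(max(err2, 0) / normX2)
    if (is.finite(rel_err) && abs(rel_err - new_rel) < tol) {
      rel_err <- new_rel
      converged <- TRUE
      break
    }
    rel_err <- new_rel
  }
  list(A = A, B = B, C = C, rel_error = rel_err, converged = converged,
       n_iter = it)
}

#' Nonnegative CP (canonical polyadic) tensor factorization
#'
#' Stage 1 of the encoding-manifold pipeline: decomposes the nonnegative
#' `neurons x stimuli x time` response tensor into `R` rank-1 nonnegative
#' components (neuron loadings, stimulus factors, temporal factors),
#' multi-clustering neurons by which stimuli they respond to and how their
#' responses unfold in time. Fitting uses hierarchical alternating
#' least squares (HALS) updates under nonnegativity, minimizing squared
#' reconstruction error; the best of `n_restarts` random restarts is kept.
#'
#' Scale convention: stimulus and temporal factor columns have unit L2
#' norm; all component magnitude lives in the neuron-factor columns, whose
#' L2 norms are reported as `component_weights`, so rows of
#' `neuron_factors` are directly comparable encoding vectors. Components
#' are ordered by decreasing weight.
#'
#' @param tensor A `response_tensor` (or plain nonnegative 3-way array).
#' @param R Number of components (rank), `>= 1`.
#' @param n_restarts Random restarts; best fit kept.
#' @param seed Integer seed making the restarts reproducible.
#' @param max_iter,tol HALS iteration cap and convergence tolerance on the
#'   change in relative error.
#' @param n_warm,warm_iter Multi-start warm-up: each restart screens
#'   `n_warm` random initializations for `warm_iter` HALS iterations and
#'   continues the best, which keeps restarts out of poor local minima.
#'
#' @return An object of class `factor_model`: `neuron_factors` (`N x R`),
#'   `stimulus_factors` (`S x R`, unit-L2 columns), `temporal_factors`
#'   (`T x R`, unit-L2 columns), `component_weights`, `rank`, `rel_error`,
#'   `converged`, `seed`.
#' @export
ntf_decompose <- function(tensor, R, n_restarts = 10, seed = 1,
                          max_iter = 500, tol = 1e-8,
                          n_warm = 4, warm_iter = 30) {
  X <- if (inherits(tensor, "response_tensor")) tensor$values else tensor
  stopifnot(length(dim(X)) == 3)
  if (any(X < 0)) stop("tensor must be nonnegative")
  d <- dim(X)
  if (R < 1) stop("R must be >= 1")
  if (R > min(d[1], d[2] * d[3])) {
    stop(sprintf("R = %d exceeds min(N, S*T) = %d", R, min(d[1], d[2] * d[3])))
  }
  normX2 <- sum(X^2)
  if (normX2 == 0) {
    ## all-zero tensor: the zero model reproduces it exactly; rel_error
    ## is defined as 0 by convention
    zf <- function(n) matrix(0, n, R)
    return(structure(list(neuron_factors = zf(d[1]),
                          stimulus_factors = zf(d[2]),
                          temporal_factors = zf(d[3]),
                          component_weights = numeric(R), rank = as.integer(R),
                          rel_error = 0, converged = TRUE, seed = seed),
                     class = "factor_model"))
  }
  X1 <- unfold3(X, 1); X2 <- unfold3(X, 2); X3 <- unfold3(X, 3)
  scale0 <- (normX2 / prod(d))^(1 / 3)
  best <- NULL
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  for (s in seq_len(n_restarts)) {
    set.seed(seed + s - 1L)
    ## multi-start warm-up: run a few iterations from several random
    ## initializations and continue only the most promising one, which
    ## makes single restarts far less likely to settle in a poor local
    ## minimum of the nonconvex objective
    warm <- NULL
    for (w in seq_len(n_warm)) {
      A <- matrix(stats::runif(d[1] * R, 0.1, 1) * scale0, d[1], R)
      B <- matrix(stats::runif(d[2] * R, 0.1, 1), d[2], R)
      C <- matrix(stats::runif(d[3] * R, 0.1, 1), d[3], R)
      cand <- hals_fit(X1, X2, X3, A, B, C, normX2,
                       max_iter = warm_iter, tol = 0)
      if (is.null(warm) || cand$rel_error < warm$rel_error) warm <- cand
    }
    fit <- hals_fit(X1, X2, X3, warm$A, warm$B, warm$C, normX2, max_iter, tol)
    if (is.null(best) || fit$rel_error < best$rel_error) best <- fit
  }
  if (!best$converged) {
    warning(sprintf(
      "HALS did not converge in %d iterations (rel_error %.3g); best iterate returned",
      max_iter, best$rel_error))
  }
  ## scale convention: unit-L2 stimulus and temporal columns
  nb <- sqrt(colSums(best$B^2)); nc <- sqrt(colSums(best$C^2))
  nb[nb == 0] <- 1; nc[nc == 0] <- 1
  A <- best$A * rep(nb * nc, each = d[1])
  B <- best$B / rep(nb, each = d[2])
  C <- best$C / rep(nc, each = d[3])
  w <- sqrt(colSums(A^2))
  ord <- order(w, decreasing = TRUE)
  structure(list(neuron_factors = A[, ord, drop = FALSE],
                 stimulus_factors = B[, ord, drop = FALSE],
                 temporal_factors = C[, ord, drop = FALSE],
                 component_weights = w[ord], rank = as.integer(R),
                 rel_error = best$rel_error, converged = best$converged,
                 seed = seed),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Nonnegative CP model: rank %d, %d neurons, rel. error %.4g%s\n",
              x$rank, nrow(x$neuron_factors), x$rel_error,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Hungarian assignment (minimum-cost perfect matching)
#'
#' Solves the square assignment problem in O(n^3); used to match CP
#' components across restarts by cosine similarity.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `p` with `p[i]` the column assigned to row `i`.
#' @export
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, v[1] is virtual column 0
  p <- integer(n + 1)      # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_of_row <- integer(n)
  for (j in seq_len(n)) assign_of_row[p[j + 1L]] <- j
  assign_of_row
}

cosine_matrix <- function(A, B) {
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  crossprod(A, B) / outer(na, nb)
}

#' Cross-restart stability of CP components
#'
#' For every pair of models (same rank, same tensor), components are put in
#' correspondence by Hungarian assignment on the neuron-factor cosine
#' similarity matrix; the score is the mean matched cosine, averaged over
#' pairs. 1 means restarts recover the same components up to permutation.
#'
#' @param models List of `factor_model`s of equal rank.
#' @return Stability score in `[0, 1]`.
#' @export
factor_stability <- function(models) {
  stopifnot(length(models) >= 2)
  ranks <- vapply(models, function(m) m$rank, numeric(1))
  if (length(unique(ranks)) != 1L) stop("models must have equal rank")
  pairs <- utils::combn(length(models), 2)
  sc <- apply(pairs, 2, function(p) {
    S <- cosine_matrix(models[[p[1]]]$neuron_factors,
                       models[[p[2]]]$neuron_factors)
    asg <- hungarian_assignment(1 - S)
    mean(S[cbind(seq_len(nrow(S)), asg)])
  })
  mean(sc)
}

#' Congruence between a fitted model and known generating factors
#'
#' Mean best-match cosine between fitted and true factor columns, averaged
#' over the three modes, after Hungarian matching on the summed cosine.
#' Used by construct-then-recover checks.
#'
#' @param model A `factor_model`.
#' @param A,B,C True nonnegative factor matrices.
#' @return Mean congruence in `[-1, 1]`.
#' @export
factor_congruence <- function(model, A, B, C) {
  Sa <- cosine_matrix(model$neuron_factors, A)
  Sb <- cosine_matrix(model$stimulus_factors, B)
  Sc <- cosine_matrix(model$temporal_factors, C)
  S <- Sa + Sb + Sc
  asg <- hungarian_assignment(-S)
  idx <- cbind(seq_len(nrow(S)), asg)
  mean((Sa[idx] + Sb[idx] + Sc[idx]) / 3)
}

#' Select the CP rank by elbow + stability
#'
#' Fits every candidate rank with `n_restarts` restarts and returns the
#' smallest rank `R` whose (a) drop in relative reconstruction error to the
#' next candidate falls below `eps_elbow` and (b) cross-restart stability
#' ([factor_stability()] of the restart models) is at least `s_min`. When
#' no candidate qualifies, the rank maximizing `stability * (1 - error)` is
#' returned with a warning.
#'
#' @param tensor A `response_tensor` or nonnegative 3-way array.
#' @param candidates Ascending integer ranks to try.
#' @param n_restarts,seed,max_iter,tol,n_warm,warm_iter Passed to the
#'   per-rank fits ([ntf_decompose()]).
#' @param eps_elbow Minimum error drop still counted as an improvement.
#' @param s_min Minimum cross-restart stability.
#'
#' @return A list: `rank`, `model` (best fit at the selected rank),
#'   `diagnostics` (data.frame with `rank`, `rel_error`, `stability`,
#'   `improvement`), `selected_by` (`"elbow"` or `"fallback"`).
#' @export
select_rank <- function(tensor, candidates = 1:12, n_restarts = 10, seed = 1,
                        eps_elbow = 0.01, s_min = 0.9,
                        max_iter = 500, tol = 1e-8,
                        n_warm = 8, warm_iter = 50) {
  stopifnot(length(candidates) >= 1, !is.unsorted(candidates))
  candidates <- as.integer(candidates)
  X <- if (inherits(tensor, "response_tensor")) tensor$values else tensor
  nr <- length(candidates)
  errs <- numeric(nr); stab <- numeric(nr)
  best_models <- vector("list", nr)
  for (k in seq_len(nr)) {
    R <- candidates[k]
    fits <- lapply(seq_len(n_restarts), function(s) {
      ntf_decompose(X, R, n_restarts = 1, seed = seed + (s - 1L) * 1000L,
                    max_iter = max_iter, tol = tol,
                    n_warm = n_warm, warm_iter = warm_iter)
    })
    errs[k] <- min(vapply(fits, function(f) f$rel_error, numeric(1)))
    best_models[[k]] <- fits[[which.min(vapply(fits, function(f) f$rel_error,
                                               numeric(1)))]]
    stab[k] <- if (n_restarts >= 2) factor_stability(fits) else 1
  }
  improvement <- c(errs[-nr] - errs[-1], NA_real_)
  ok <- which(!is.na(improvement) & improvement < eps_elbow & stab >= s_min)
  diagnostics <- data.frame(rank = candidates, rel_error = errs,
                            stability = stab, improvement = improvement)
  if (length(ok)) {
    k <- ok[1]
    selected_by <- "elbow"
  } else {
    k <- which.max(stab * (1 - errs))
    selected_by <- "fallback"
    warning("no candidate rank met the elbow+stability criteria; ",
            "returning argmax of stability * (1 - error)")
  }
  list(rank = candidates[k], model = best_models[[k]],
       diagnostics = diagnostics, selected_by = selected_by)
}

#' Export a factor model to CSV files
#'
#' Writes `neuron_factors.csv`, `stimulus_factors.csv`,
#' `temporal_factors.csv` and `model_info.json` into `dir`.
#'
#' @param model A `factor_model`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_factor_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(model$neuron_factors),
                   file.path(dir, "neuron_factors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$stimulus_factors),
                   file.path(dir, "stimulus_factors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model$temporal_factors),
                   file.path(dir, "temporal_factors.csv"), row.names = FALSE)
  jsonlite::write_json(list(rank = model$rank, rel_error = model$rel_error,
                            component_weights = model$component_weights,
                            converged = model$converged, seed = model$seed),
                       file.path(dir, "model_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
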