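#' Diffusion-map embedding of a data graph
#'
#' Infers the encoding manifold from the data graph by spectral analysis
#' of its diffusion (random-walk) operator. The kernel is first
#' density-normalized, `W_alpha = D^-alpha W D^-alpha` (with `alpha = 1`
#' the walk approximates the Laplace-Beltrami operator, removing sampling
#' density effects), then row-normalized to a Markov matrix `P`. The
#' diffusion coordinates are `lambda_k^t * psi_k` for the top `m`
#' nontrivial right eigenvectors `psi_k` of `P`.
#'
#' The globally constant eigenvector (eigenvalue 1) is excluded. When the
#' graph is disconnected the unit eigenvalue has multiplicity equal to the
#' number of connected components; the remaining unit-eigenvalue
#' eigenvectors are kept as coordinates - they are the piecewise-constant
#' component indicators that separate the components in the embedding -
#' and are computed deterministically (Gram-Schmidt of the component
#' indicators against the constant), with component labels reported
#' alongside. Eigenvector signs are fixed by making each vector's
#' largest-magnitude entry positive.
#'
#' @param graph An [encoding_graph][build_graph] (or symmetric nonnegative
#'   weight matrix).
#' @param m Number of nontrivial diffusion coordinates.
#' @param t Diffusion time (power applied to the eigenvalues).
#' @param alpha Density-normalization exponent in `[0, 1]`.
#'
#' @return Object of class `diffusion_embedding`: `eigenvalues`
#'   (`1 = lambda_0 >= lambda_1 >= ...`, length `m + 1`), `coordinates`
#'   (`N x m`, trivial eigenvector excluded), `t`, `alpha`,
#'   `unit_multiplicity` (multiplicity of eigenvalue 1), `components`
#'   (per-node connected-component label).
#' @export
diffusion_map <- function(graph, m = 10, t = 1, alpha = 1) {
  W <- if (inherits(graph, "encoding_graph")) graph$weights else as.matrix(graph)
  n <- nrow(W)
  if (n < 2) stop("graph needs at least 2 nodes")
  if (max(abs(W - t(W))) > 1e-10) stop("weight matrix must be symmetric")
  if (m > n - 1) {
    warning(sprintf("m = %d exceeds the available nontrivial spectrum; using %d",
                    m, n - 1L))
    m <- n - 1L
  }
  deg <- rowSums(W)
  if (any(deg <= 0)) {
    stop("graph has isolated node(s) with zero degree; ",
         "remove them or connect them before embedding")
  }
  comp <- graph_components(W)
  ncomp <- max(comp)
  ## density normalization and symmetric conjugation of the Markov matrix
  Wa <- W / outer(deg^alpha, deg^alpha)
  da <- rowSums(Wa)
  s <- 1 / sqrt(da)
  Smat <- Wa * outer(s, s)
  Smat <- (Smat + t(Smat)) / 2
  eig <- eigen(Smat, symmetric = TRUE)
  lambda <- eig$values
  V <- eig$vectors
  ## deterministic basis for the unit eigenspace: constant first, then
  ## component indicators orthogonalized against it (disjoint supports
  ## make them orthogonal to each other already)
  if (ncomp >= 1) {
    sq <- sqrt(da)
    basis <- matrix(0, n, ncomp)
    v0 <- sq / sqrt(sum(da))
    basis[, 1] <- v0
    if (ncomp > 1) {
      for (cidx in seq_len(ncomp - 1L)) {
        b <- ifelse(comp == cidx, sq, 0)
        for (j in seq_len(cidx)) b <- b - sum(b * basis[, j]) * basis[, j]
        basis[, cidx + 1L] <- b / sqrt(sum(b^2))
      }
    }
    V[, seq_len(ncomp)] <- basis
    lambda[seq_len(ncomp)] <- 1
  }
  lambda <- pmin(pmax(lambda, -1), 1)
  psi <- V * s   # right eigenvectors of P
  ## sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(psi))) {
    piv <- which.max(abs(psi[, j]))
    if (psi[piv, j] < 0) psi[, j] <- -psi[, j]
  }
  keep <- 1L + seq_len(m)
  lt <- sign(lambda[keep]) * abs(lambda[keep])^t  # safe for negative lambda
  coords <- psi[, keep, drop = FALSE] * rep(lt, each = n)
  colnames(coords) <- paste0("coord_", seq_len(m))
  rownames(coords) <- rownames(W)
  structure(list(eigenvalues = lambda[seq_len(m + 1L)], coordinates = coords,
                 t = t, alpha = alpha,
                 unit_multiplicity = sum(lambda > 1 - 1e-8),
                 components = comp),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf(
    "Diffusion embedding: %d points, %d coordinates (t = %g, alpha = %g)\n",
    nrow(x$coordinates), ncol(x$coordinates), x$t, x$alpha))
  cat("  eigenvalues:", paste(sprintf("%.3f", utils::head(x$eigenvalues, 6)),
                              collapse = " "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' Diffusion embedding of a plain 0/1 adjacency matrix
#'
#' Applies the same spectral pipeline as [diffusion_map()] directly to a
#' given unweighted graph; used for stochastic-block-model demonstrations
#' and for analyzing pipeline-produced graphs as adjacency structures.
#' Defaults to `alpha = 0` (the plain random walk on the given graph).
#'
#' @param adjacency Symmetric 0/1 matrix (no self-loops required).
#' @param m,t,alpha As in [diffusion_map()].
#' @return A `diffusion_embedding`.
#' @export
embed_adjacency <- function(adjacency, m = 10, t = 1, alpha = 0) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 0) {
    stop("adjacency must be symmetric")
  }
  offdiag <- A
  diag(offdiag) <- 0
  if (!all(offdiag %in% c(0, 1))) stop("adjacency must be 0/1")
  if (all(offdiag == 0)) {
    stop("adjacency has no edges between distinct nodes (isolated nodes ",
         "only); diffusion is degenerate - supply a graph with edges")
  }
  deg <- rowSums(offdiag)
  if (any(deg == 0)) {
    stop(sprintf("%d isolated node(s) in adjacency; drop them before embedding",
                 sum(deg == 0)))
  }
  diffusion_map(offdiag, m = m, t = t, alpha = alpha)
}

#' Export diffusion coordinates as CSV
#' @param embedding A `diffusion_embedding`.
#' @param path Output CSV path.
#' @param neuron_ids Optional id column.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, neuron_ids = NULL) {
  df <- as.data.frame(embedding$coordinates)
  if (is.null(neuron_ids)) {
    neuron_ids <- rownames(embedding$coordinates)
    if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(df))
  }
  df <- cbind(data.frame(neuron_id = neuron_ids,
                         component = embedding$components), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
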