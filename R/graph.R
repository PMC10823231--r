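#' Build the weighted data graph over neurons (iterated adaptive kernel)
#'
#' Connects neurons whose encoding vectors (rows of the neuron-factor
#' matrix) are similar, with a locally adaptive Gaussian kernel
#' `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))`, where `d_ij` is Euclidean
#' distance and `sigma_i` is the distance from point `i` to its `k`-th
#' nearest neighbor (self-tuning bandwidth). Each point starts from its
#' `k` nearest neighbors (ties at the k-th distance included); the
#' neighborhoods are then refined iteratively: an edge is dropped when its
#' weight falls below a fraction `theta` of the point's median retained
#' edge weight, and the pass is repeated until a fixed point (or
#' `max_passes`). This prunes edges that straddle density gaps, so
#' clusters separate cleanly. The directed neighborhoods are finally
#' symmetrized by the maximum rule; self-weights are 1.
#'
#' @param factors `N x R` matrix of neuron encoding vectors, or a
#'   `factor_model` (its `neuron_factors` are used).
#' @param k Neighbor count for both the bandwidth and the initial
#'   neighborhood; must satisfy `k < N`.
#' @param theta Pruning fraction of the median retained weight.
#' @param max_passes Cap on refinement passes.
#'
#' @return Object of class `encoding_graph`: `weights` (symmetric `N x N`,
#'   entries in `[0, 1]`, unit diagonal), `neighborhoods` (per-point
#'   retained neighbor indices, pre-symmetrization), `scales` (`sigma_i`),
#'   `n_iterations` (refinement passes used), `k`, `theta`.
#' @export
build_graph <- function(factors, k = 10, theta = 0.1, max_passes = 5) {
  X <- if (inherits(factors, "factor_model")) factors$neuron_factors else
    as.matrix(factors)
  if (!all(is.finite(X))) stop("factor rows must be finite")
  n <- nrow(X)
  if (k >= n) stop(sprintf("k = %d must be smaller than N = %d", k, n))
  D <- as.matrix(stats::dist(X))
  eps <- 1e-12
  ## self-tuning bandwidth: distance to the k-th nearest other point
  sigma <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sort(d, partial = k)[k]
  }, numeric(1))
  sigma <- pmax(sigma, eps)
  W <- exp(-D^2 / outer(sigma, sigma))
  ## initial directed neighborhoods: k nearest, ties at the k-th included
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    kd <- sort(d, partial = k)[k]
    nbr[[i]] <- which(d <= kd + eps)
  }
  ## iterated refinement: prune edges below theta * median retained weight
  passes <- 0L
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      wi <- W[i, nbr[[i]]]
      if (!length(wi)) next
      keep <- wi >= theta * stats::median(wi)
      if (!all(keep)) {
        nbr[[i]] <- nbr[[i]][keep]
        changed <- TRUE
      }
    }
    passes <- passes + 1L
    if (!changed || passes >= max_passes) break
  }
  ## symmetrize by the maximum rule
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, nbr[[i]]] <- W[i, nbr[[i]]]
  S <- pmax(A, t(A))
  diag(S) <- 1
  rownames(S) <- colnames(S) <- rownames(X)
  structure(list(weights = S, neighborhoods = nbr, scales = sigma,
                 n_iterations = passes, k = k, theta = theta),
            class = "encoding_graph")
}

#' @export
print.encoding_graph <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- (sum(x$weights > 0) - n) / 2
  cat(sprintf("Encoding graph: %d neurons, %d edges, %d refinement pass(es)\n",
              n, ne, x$n_iterations))
  invisible(x)
}

#' Connected components of an encoding graph
#' @param graph An `encoding_graph` or symmetric weight/adjacency matrix.
#' @return Integer component label per node.
#' @export
graph_components <- function(graph) {
  W <- if (inherits(graph, "encoding_graph")) graph$weights else graph
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Export a graph as an edge-list CSV
#' @param graph An `encoding_graph`.
#' @param path Output CSV path (columns `i`, `j`, `weight`, upper triangle).
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  W <- graph$weights
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(i = ut[, 1], j = ut[, 2],
                              weight = W[ut]),
                   path, row.names = FALSE)
  invisible(path)
}
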