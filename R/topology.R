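#' Density-based hierarchical clustering of the manifold
#'
#' Decides which neurons form density clusters on the embedded manifold,
#' HDBSCAN-style: pairwise mutual-reachability distances
#' `max(core_i, core_j, d_ij)` (with `core_i` the distance to the
#' `min_cluster_size`-th neighbor) are single-linkage clustered, the
#' dendrogram is condensed by discarding splits smaller than
#' `min_cluster_size`, and flat clusters are extracted by maximizing
#' density persistence (excess of mass) over the condensed tree. Points
#' never captured by a selected cluster are noise (label 0).
#'
#' The root of the condensed tree competes for selection like any other
#' cluster (its birth is the first split), so a connected, uniformly
#' sampled manifold comes out as one cluster rather than all noise.
#'
#' When given a `diffusion_embedding`, the coordinates are first rescaled
#' to a longer diffusion time `t_cluster` (each coordinate multiplied by
#' `lambda_k^(t_cluster - t)`): cluster structure lives in the slow,
#' near-unit eigenvalues, and a longer diffusion time lets them dominate
#' the fast within-cluster modes that share the top of the spectrum at
#' `t = 1`. The default picks `t_cluster` so the smallest kept eigenvalue
#' is attenuated to 0.1.
#'
#' @param embedding A [diffusion_embedding][diffusion_map] (its
#'   coordinates are clustered) or a numeric matrix of points.
#' @param min_cluster_size Smallest split still counted as a cluster;
#'   default `max(5, N / 100)`.
#' @param t_cluster Diffusion time of the clustering view (only used for
#'   `diffusion_embedding` input); `NULL` = adaptive as above.
#' @param selection_epsilon Minimum split scale: dendrogram heights below
#'   this are treated as one density level, so splits finer than
#'   `selection_epsilon` can never out-persist their parent cluster
#'   (guards against fragmentation by near-duplicate points and by local
#'   density modes on a connected manifold). `NULL` = 20\% of the median
#'   pairwise distance.
#'
#' @return Object of class `topology_report` with `cluster_labels`
#'   (integer, 0 = noise), `cluster_persistence` (per-cluster stability),
#'   `n_clusters`, `clustered_fraction`, `largest_cluster_fraction`,
#'   `verdict` (`"clustered"` or `"continuous"`), and `local_dim` (`NULL`
#'   until filled by [local_intrinsic_dim()] via [topology_summary()]).
#' @export
density_cluster <- function(embedding, min_cluster_size = NULL,
                            t_cluster = NULL, selection_epsilon = NULL) {
  X <- if (inherits(embedding, "diffusion_embedding")) {
    cluster_view(embedding, t_cluster)
  } else {
    as.matrix(embedding)
  }
  n <- nrow(X)
  if (is.null(min_cluster_size)) min_cluster_size <- max(5, round(n / 100))
  mcs <- max(2L, as.integer(min_cluster_size))
  if (n < 2 * mcs) {
    warning(sprintf(
      "only %d points for min_cluster_size %d; returning a single cluster",
      n, mcs))
    return(new_topology_report(rep(1L, n), c(`1` = 0)))
  }
  D <- as.matrix(stats::dist(X))
  core <- vapply(seq_len(n), function(i) {
    sort(D[i, -i], partial = mcs)[mcs]
  }, numeric(1))
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0
  if (is.null(selection_epsilon)) {
    selection_epsilon <- 0.2 * stats::median(D[upper.tri(D)])
  }
  hc <- stats::hclust(stats::as.dist(MR), method = "single")
  ct <- condense_tree(hc, n, mcs, h_floor = selection_epsilon)
  sel <- extract_eom_clusters(ct)
  labels <- label_points(ct, sel, n)
  persistence <- ct$own_stability[sel]
  names(persistence) <- seq_along(sel)
  ## relabel clusters 1..K by decreasing size
  K <- length(sel)
  if (K) {
    sizes <- tabulate(labels, nbins = K)
    ord <- order(sizes, decreasing = TRUE)
    relab <- integer(K); relab[ord] <- seq_len(K)
    nz <- labels != 0L
    labels[nz] <- relab[labels[nz]]
    persistence <- persistence[ord]
    names(persistence) <- seq_len(K)
  }
  new_topology_report(labels, persistence)
}

# Rescale diffusion coordinates to a longer diffusion time for
# clustering; lambda^t_cluster with t_cluster chosen so the smallest kept
# nontrivial eigenvalue is damped to `atten`.
cluster_view <- function(embedding, t_cluster = NULL, atten = 0.1) {
  lam <- embedding$eigenvalues[-1]
  keep <- seq_len(ncol(embedding$coordinates))
  lam <- lam[keep]
  if (is.null(t_cluster)) {
    lmin <- min(abs(lam))
    t_cluster <- if (lmin <= 0 || lmin >= 1 - 1e-10) embedding$t
    else min(1000, max(embedding$t, log(atten) / log(lmin)))
  }
  scale <- ifelse(abs(lam) > 0,
                  sign(lam) * abs(lam)^(t_cluster - embedding$t), 1)
  embedding$coordinates * rep(scale, each = nrow(embedding$coordinates))
}

new_topology_report <- function(labels, persistence, local_dim = NULL) {
  n <- length(labels)
  K <- length(persistence)
  sizes <- if (K) tabulate(labels, nbins = K) else integer(0)
  clustered_fraction <- mean(labels != 0L)
  largest <- if (K) max(sizes) / n else 0
  verdict <- if (K >= 2 && largest < 0.8) "clustered" else "continuous"
  structure(list(cluster_labels = labels,
                 cluster_persistence = persistence,
                 n_clusters = K,
                 clustered_fraction = clustered_fraction,
                 largest_cluster_fraction = largest,
                 local_dim = local_dim,
                 verdict = verdict),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "Topology report: %d cluster(s), %.0f%% of points clustered -> %s\n",
    x$n_clusters, 100 * x$clustered_fraction, x$verdict))
  if (!is.null(x$local_dim)) {
    cat(sprintf("  median local intrinsic dimension: %.2f\n",
                stats::median(x$local_dim)))
  }
  invisible(x)
}

## ---- condensed-tree internals ------------------------------------------

# Members of every internal node of an hclust tree.
merge_members <- function(merge, n) {
  nm <- nrow(merge)
  members <- vector("list", nm)
  for (i in seq_len(nm)) {
    get1 <- function(x) if (x < 0) -x else members[[x]]
    members[[i]] <- c(get1(merge[i, 1]), get1(merge[i, 2]))
  }
  members
}

# Condense an hclust dendrogram: walk from the root, discarding splits
# smaller than mcs (their points "fall out" of the running cluster at the
# split's density level lambda = 1/height). Returns per-cluster birth
# levels, parents, own stabilities, and each point's fall-out record.
condense_tree <- function(hc, n, mcs, h_floor = 0) {
  merge <- hc$merge
  heights <- hc$height
  members <- merge_members(merge, n)
  sizes <- lengths(members)
  h_eps <- max(1e-12, min(heights[heights > 0], Inf) * 1e-6, h_floor)
  lam <- 1 / pmax(heights, h_eps)

  parent <- integer(0)        # parent cluster id (0 for root)
  birth <- numeric(0)         # birth lambda per cluster
  own_stab <- numeric(0)      # own (excess-of-mass) stability
  child_clusters <- list()    # cluster ids of direct child clusters
  point_cluster <- integer(n) # cluster each point fell out of
  point_lambda <- numeric(n)

  root_node <- nrow(merge)
  birth[1] <- lam[root_node]  # root is born at its first split
  parent[1] <- 0L
  own_stab[1] <- 0
  child_clusters[[1]] <- integer(0)
  stack <- list(list(node = root_node, cid = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- fr$node; cid <- fr$cid
    repeat {
      l <- lam[node]
      ch <- merge[node, ]
      csz <- ifelse(ch < 0, 1L, sizes[pmax(ch, 1L)])
      big <- csz >= mcs
      if (all(big)) {
        ## true split: the cluster dies into two new clusters
        for (j in 1:2) {
          ncid <- length(birth) + 1L
          birth[ncid] <- l
          parent[ncid] <- cid
          own_stab[ncid] <- 0
          child_clusters[[ncid]] <- integer(0)
          child_clusters[[cid]] <- c(child_clusters[[cid]], ncid)
          own_stab[cid] <- own_stab[cid] + csz[j] * (l - birth[cid])
          stack[[length(stack) + 1L]] <- list(node = ch[j], cid = ncid)
        }
        break
      }
      drop_child <- function(x) {
        pts <- if (x < 0) -x else members[[x]]
        point_cluster[pts] <<- cid
        point_lambda[pts] <<- l
        own_stab[cid] <<- own_stab[cid] + length(pts) * (l - birth[cid])
      }
      if (any(big)) {
        ## small side falls out; the cluster continues down the big side
        drop_child(ch[!big][1])
        node <- ch[big][1]
        if (node < 0) { drop_child(node); break }  # only when mcs == 1
      } else {
        drop_child(ch[1]); drop_child(ch[2])
        break
      }
    }
  }
  list(parent = parent, birth = birth, own_stability = own_stab,
       child_clusters = child_clusters,
       point_cluster = point_cluster, point_lambda = point_lambda)
}

# Excess-of-mass cluster extraction over the condensed tree: bottom-up,
# a cluster beats its selected descendants when its own stability is at
# least their summed best stability. Returns selected cluster ids.
extract_eom_clusters <- function(ct) {
  ncl <- length(ct$birth)
  best <- numeric(ncl)
  keep <- logical(ncl)
  for (cid in rev(seq_len(ncl))) {   # children have larger ids than parents
    ch <- ct$child_clusters[[cid]]
    sub <- if (length(ch)) sum(best[ch]) else 0
    if (ct$own_stability[cid] >= sub || !length(ch)) {
      best[cid] <- ct$own_stability[cid]
      keep[cid] <- TRUE
    } else {
      best[cid] <- sub
      keep[cid] <- FALSE
    }
  }
  ## top-down: a selected cluster masks its descendants
  selected <- integer(0)
  visit <- c(1L)
  while (length(visit)) {
    cid <- visit[1]; visit <- visit[-1]
    if (keep[cid]) {
      selected <- c(selected, cid)
    } else {
      visit <- c(visit, ct$child_clusters[[cid]])
    }
  }
  sort(selected)
}

label_points <- function(ct, selected, n) {
  ## map each cluster to its nearest selected ancestor (or 0)
  ncl <- length(ct$birth)
  sel_map <- integer(ncl)
  in_sel <- logical(ncl); in_sel[selected] <- TRUE
  for (cid in seq_len(ncl)) {
    cur <- cid
    while (cur != 0L && !in_sel[cur]) cur <- ct$parent[cur]
    sel_map[cid] <- if (cur == 0L) 0L else match(cur, selected)
  }
  sel_map[ct$point_cluster]
}

## ---- other topology statistics -----------------------------------------

#' Local intrinsic dimensionality (maximum-likelihood estimate)
#'
#' Per-point Levina-Bickel estimator from nearest-neighbor distance
#' ratios: `dim_i = [(1/(k-1)) * sum_{j<k} log(T_k / T_j)]^-1`, with `T_j`
#' the distance from point `i` to its `j`-th nearest neighbor. Invariant
#' to global isotropic rescaling. Duplicate-point distances are floored at
#' `1e-9` times the mean pairwise distance.
#'
#' @param points Numeric matrix (or `diffusion_embedding`).
#' @param k Neighborhood size, `>= 5`.
#' @return Numeric vector of per-point dimension estimates.
#' @export
local_intrinsic_dim <- function(points, k = 15) {
  X <- if (inherits(points, "diffusion_embedding")) points$coordinates
  else as.matrix(points)
  n <- nrow(X)
  if (k < 5) stop("k must be >= 5")
  if (k >= n) stop("k must be smaller than the number of points")
  D <- as.matrix(stats::dist(X))
  floor_d <- max(mean(D), .Machine$double.xmin) * 1e-9
  vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i], partial = seq_len(k))[seq_len(k)]
    d <- pmax(d, floor_d)
    1 / mean(log(d[k] / d[-k]))
  }, numeric(1))
}

#' Local density of like-typed neighbors on the data graph
#'
#' For each neuron, the edge-weighted fraction of its graph neighbors that
#' share its label; used to display how strongly a categorical property
#' (cell type, layer, putative E/I) concentrates locally on the manifold.
#'
#' @param graph An [encoding_graph][build_graph] (or symmetric weight
#'   matrix with unit diagonal).
#' @param labels Per-neuron category labels (any atomic type).
#' @return Numeric vector of scores in `[0, 1]`; isolated neurons score 0
#'   and are flagged in the `"isolated"` attribute.
#' @export
like_type_density <- function(graph, labels) {
  W <- if (inherits(graph, "encoding_graph")) graph$weights else as.matrix(graph)
  n <- nrow(W)
  if (length(labels) != n) stop("labels must cover all neurons")
  A <- W
  diag(A) <- 0
  same <- outer(labels, labels, `==`)
  tot <- rowSums(A)
  isolated <- tot <= 0
  score <- ifelse(isolated, 0, rowSums(A * same) / ifelse(isolated, 1, tot))
  attr(score, "isolated") <- isolated
  score
}

#' Reorder a weight matrix to expose block structure
#'
#' Permutes rows/columns so that same-labeled neurons are contiguous
#' (blocks ordered by decreasing size) and, within a block, sorted by
#' decreasing degree. A diagonally dominant picture indicates a clustered
#' graph; widespread off-block weight indicates a continuous one.
#'
#' @param graph An `encoding_graph` or symmetric weight matrix.
#' @param labels Per-neuron cluster labels (e.g. from [density_cluster()]).
#' @return List with `weights` (permuted matrix), `permutation` (original
#'   index of each new row; apply `order(permutation)` to invert), and
#'   `block_weight_fraction` (share of total off-diagonal weight inside
#'   the diagonal blocks).
#' @export
order_adjacency <- function(graph, labels) {
  W <- if (inherits(graph, "encoding_graph")) graph$weights else as.matrix(graph)
  n <- nrow(W)
  if (length(labels) != n) stop("labels must cover all neurons")
  deg <- rowSums(W)
  f <- factor(labels)
  sizes <- table(f)
  lev_ord <- names(sort(sizes, decreasing = TRUE))
  perm <- unlist(lapply(lev_ord, function(lv) {
    idx <- which(f == lv)
    idx[order(deg[idx], decreasing = TRUE)]
  }), use.names = FALSE)
  Wp <- W[perm, perm]
  offd <- W; diag(offd) <- 0
  same <- outer(labels, labels, `==`)
  bwf <- if (sum(offd) > 0) sum(offd[same]) / sum(offd) else NA_real_
  list(weights = Wp, permutation = perm, block_weight_fraction = bwf)
}

#' Full clustered-vs-continuous topology summary
#'
#' Runs [density_cluster()] and [local_intrinsic_dim()] on an embedding
#' and combines them into one report. The verdict is `"clustered"` when at
#' least two density clusters exist and no single cluster holds 80% of
#' the points, `"continuous"` otherwise.
#'
#' @param embedding A `diffusion_embedding` or coordinate matrix.
#' @param min_cluster_size Passed to [density_cluster()].
#' @param k_dim Neighborhood size for [local_intrinsic_dim()].
#' @return A `topology_report` with `local_dim` filled in.
#' @export
topology_summary <- function(embedding, min_cluster_size = NULL, k_dim = 15) {
  report <- density_cluster(embedding, min_cluster_size)
  X <- if (inherits(embedding, "diffusion_embedding")) embedding$coordinates
  else as.matrix(embedding)
  if (nrow(X) > k_dim) {
    report$local_dim <- local_intrinsic_dim(X, k = k_dim)
  }
  report
}

#' Write a topology report (JSON summary + per-neuron CSV)
#' @param report A `topology_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_topology_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    n_clusters = report$n_clusters,
    clustered_fraction = report$clustered_fraction,
    largest_cluster_fraction = report$largest_cluster_fraction,
    verdict = report$verdict,
    cluster_persistence = as.numeric(report$cluster_persistence)
  ), file.path(dir, "topology_summary.json"), auto_unbox = TRUE, digits = NA)
  df <- data.frame(neuron = seq_along(report$cluster_labels),
                   cluster = report$cluster_labels)
  if (!is.null(report$local_dim)) df$local_dim <- report$local_dim
  utils::write.csv(df, file.path(dir, "topology_perneuron.csv"),
                   row.names = FALSE)
  invisible(dir)
}
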