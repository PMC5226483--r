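#' Graph metrics for weighted structural networks
#'
#' The connection weight encodes coupling strength, so for path-based metrics
#' an edge's length is the reciprocal of its weight (stronger connections are
#' shorter). Disconnected pairs have infinite path length and contribute zero
#' to efficiency sums, making the harmonic-mean characteristic path length
#' robust to fragmentation; no largest-component restriction is applied.
#'
#' @name graph-metrics
NULL

as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

edge_lengths <- function(g) 1 / igraph::E(g)$weight

#' Weighted shortest-path length matrix
#'
#' All-pairs shortest path lengths with edge length `1/weight`; `Inf` marks
#' disconnected pairs and the diagonal is 0.
#'
#' @param net A [weighted_network()].
#' @return A symmetric numeric matrix of path lengths.
#' @export
shortest_paths_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_edges(net) == 0) {
    n <- nrow(net$weights)
    L <- matrix(Inf, n, n)
    diag(L) <- 0
    return(L)
  }
  g <- as_igraph(net)
  L <- igraph::distances(g, weights = edge_lengths(g), algorithm = "dijkstra")
  dimnames(L) <- dimnames(net$weights)
  L
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs:
#' `Eg = (1/(N(N-1))) * sum_{i != j} 1/L_ij`, with disconnected pairs
#' contributing zero.
#'
#' @param paths A path-length matrix from [shortest_paths_matrix()], or a
#'   [weighted_network()].
#' @return A single number in `[0, Inf)`.
#' @export
global_efficiency <- function(paths) {
  if (inherits(paths, "weighted_network")) paths <- shortest_paths_matrix(paths)
  n <- nrow(paths)
  if (n < 2) return(0)
  inv <- 1 / paths
  inv[!is.finite(inv)] <- 0 # kills diagonal (1/0) and disconnected (1/Inf)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length (harmonic mean)
#'
#' `Lp = 1 / [ (1/(N(N-1))) * sum_{i != j} 1/L_ij ]` — the reciprocal of
#' global efficiency, so `Lp * Eg = 1` identically. A fully disconnected
#' network has `Lp = Inf` (with a warning).
#'
#' @inheritParams global_efficiency
#' @return A single positive number, possibly `Inf`.
#' @export
characteristic_path_length <- function(paths) {
  eg <- global_efficiency(paths)
  if (eg == 0) {
    warn("network has no finite path between any pair; Lp is infinite")
    return(Inf)
  }
  1 / eg
}

#' Clustering coefficient
#'
#' Per node, the fraction of realized edges among its neighbors,
#' `E_i / (D_i (D_i - 1) / 2)`, computed on the binarized topology of the
#' thresholded graph; nodes of degree < 2 contribute 0. `Cp` is the mean
#' over all N nodes. A weighted variant (Onnela-style geometric mean of
#' normalized triangle weights) is available via `weighted = TRUE` but is
#' not the default.
#'
#' @param net A [weighted_network()].
#' @param weighted Use the weighted geometric-mean variant.
#' @return Mean clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  A <- (net$weights > 0) * 1
  k <- rowSums(A)
  if (!weighted) {
    tri <- diag(A %*% A %*% A) / 2 # E_i: edges among neighbors of i
    ci <- ifelse(k >= 2, tri / (k * (k - 1) / 2), 0)
  } else {
    What <- net$weights / max(net$weights)
    W3 <- What^(1 / 3)
    tri_w <- diag(W3 %*% W3 %*% W3)
    ci <- ifelse(k >= 2, tri_w / (k * (k - 1)), 0)
  }
  mean(ci)
}

#' Local efficiency
#'
#' `Eloc = (1/N) * sum_i Eg(G_i)` where `G_i` is the weighted subgraph
#' induced on the neighbors of node `i` (node `i` excluded); a subgraph with
#' fewer than two nodes has efficiency 0.
#'
#' @param net A [weighted_network()].
#' @return A single non-negative number.
#' @export
local_efficiency <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$weights
  n <- nrow(W)
  e <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- weighted_network(W[nb, nb, drop = FALSE],
                            region_atlas(sprintf("n%d", nb)))
    global_efficiency(sub)
  }, numeric(1))
  mean(e)
}

#' Nodal betweenness centrality and degree
#'
#' Freeman betweenness on the weighted graph (edge length `1/weight`):
#' `B(i) = sum over unordered pairs {j,k}, j != i != k, of d_jk(i)/d_jk`,
#' the fraction of shortest j-k paths passing through `i`. Reported
#' unnormalized by default; `normalized = TRUE` divides by
#' `(N-1)(N-2)/2` for cross-size comparison. A node of degree <= 1 has
#' betweenness 0.
#'
#' @param net A [weighted_network()].
#' @param normalized Divide by the number of possible pairs.
#' @return A tibble with columns `index`, `label`, `degree`, `betweenness`.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  n <- nrow(net$weights)
  deg <- as.integer(rowSums(net$weights > 0))
  if (n_edges(net) == 0) {
    b <- numeric(n)
  } else {
    g <- as_igraph(net)
    b <- igraph::betweenness(g, directed = FALSE, weights = edge_lengths(g),
                             normalized = FALSE)
    b <- as.numeric(b)
  }
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  tibble::tibble(index = net$atlas$index, label = net$atlas$label,
                 degree = deg, betweenness = b)
}

#' @rdname betweenness_centrality
#' @export
nodal_metrics <- betweenness_centrality

#' Global network metrics for one network
#'
#' Computes Cp, Lp, Eg, Eloc; when `n_nulls > 0`, also the normalized
#' small-world parameters gamma = Cp/<Cp_rand>, lambda = Lp/<Lp_rand>, and
#' sigma = gamma/lambda against degree-preserving random networks (see
#' [small_worldness()]).
#'
#' @param net A [weighted_network()].
#' @param n_nulls Number of random networks for normalization (0 skips it).
#' @param swaps_per_edge Rewiring effort per null (default 10).
#' @param seed Master seed for the null ensemble (required if `n_nulls > 0`).
#' @param weighted_cp Use the weighted clustering variant.
#' @return A one-row tibble: `Cp`, `Lp`, `Eg`, `Eloc` (+ `gamma`, `lambda`,
#'   `sigma` when normalized).
#' @export
#' @examples
#' s <- generate_subject(cohort_spec(n_regions = 30), "NC", seed = 7)
#' global_metrics(build_weight_matrix(s))
global_metrics <- function(net, n_nulls = 0, swaps_per_edge = 10, seed = NULL,
                           weighted_cp = FALSE) {
  stopifnot(inherits(net, "weighted_network"))
  L <- shortest_paths_matrix(net)
  eg <- global_efficiency(L)
  out <- tibble::tibble(
    Cp = clustering_coefficient(net, weighted = weighted_cp),
    Lp = if (eg > 0) 1 / eg else Inf,
    Eg = eg,
    Eloc = local_efficiency(net)
  )
  if (n_nulls > 0) {
    if (is.null(seed)) abort("a seed is required for null normalization",
                             class = "wmnet_validation_error")
    sw <- small_worldness(net, n_nulls = n_nulls, swaps_per_edge = swaps_per_edge,
                          seed = seed, weighted_cp = weighted_cp,
                          cp_real = out$Cp, lp_real = out$Lp)
    out <- dplyr::bind_cols(out, sw[c("gamma", "lambda", "sigma")])
  }
  out
}
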