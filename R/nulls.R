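#' Degree-preserving random rewiring
#'
#' Randomizes the topology by repeated double-edge swaps: two edges (a,b)
#' and (c,d) are replaced by (a,d) and (c,b) whenever that creates neither a
#' self-loop nor a multi-edge. Weights travel with their edges, so the degree
#' sequence and the multiset of edge weights are preserved exactly — the
#' standard null model for weighted small-world normalization.
#'
#' @param net A [weighted_network()] with at least 2 edges.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed; the draw is a pure function of `(net, seed)`.
#' @return A rewired [weighted_network()]. If no legal swap succeeded the
#'   input topology is returned with a warning.
#' @export
#' @examples
#' net <- build_weight_matrix(generate_subject(cohort_spec(n_regions = 30), "NC", 1))
#' null <- rewire_network(net, seed = 42)
#' identical(sort(rowSums(null$weights > 0)), sort(rowSums(net$weights > 0)))
rewire_network <- function(net, swaps_per_edge = 10, seed) {
  stopifnot(inherits(net, "weighted_network"))
  m <- n_edges(net)
  if (m < 2) {
    abort("rewiring needs a network with at least 2 edges",
          class = "wmnet_validation_error")
  }
  res <- local_seed(seed, rewire_swap(net$weights, as.integer(swaps_per_edge * m)))
  if (res$swaps == 0) {
    warn("no legal double-edge swap succeeded; returning the input topology")
  }
  weighted_network(res$weights, net$atlas)
}

#' Small-world parameters via a null ensemble
#'
#' Normalizes clustering and path length by their means over `n_nulls`
#' degree-preserving random networks: `gamma = Cp / <Cp_rand>`,
#' `lambda = Lp / <Lp_rand>`, `sigma = gamma / lambda`. A small-world
#' network combines random-like path lengths (lambda near 1) with excess
#' clustering (gamma > 1), giving sigma > 1. Per-null seeds derive from
#' `seed` by a fixed counter scheme, so the ensemble is reproducible
#' draw-by-draw.
#'
#' @param net A [weighted_network()].
#' @param n_nulls Ensemble size (default 100).
#' @param swaps_per_edge Rewiring effort per null.
#' @param seed Integer master seed.
#' @param weighted_cp Use the weighted clustering variant throughout.
#' @param cp_real,lp_real Precomputed real-network Cp and Lp (skips
#'   recomputation).
#' @return A one-row tibble `gamma`, `lambda`, `sigma`, `n_nulls`, with the
#'   per-null Cp/Lp values attached as attribute `"ensemble"`.
#' @export
small_worldness <- function(net, n_nulls = 100, swaps_per_edge = 10, seed,
                            weighted_cp = FALSE, cp_real = NULL, lp_real = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_nulls < 1) abort("n_nulls must be >= 1", class = "wmnet_validation_error")
  if (is.null(cp_real)) cp_real <- clustering_coefficient(net, weighted = weighted_cp)
  if (is.null(lp_real)) lp_real <- characteristic_path_length(net)

  nulls <- purrr::map(seq_len(n_nulls), function(k) {
    null <- rewire_network(net, swaps_per_edge = swaps_per_edge,
                           seed = derive_seed(seed, k))
    c(cp = clustering_coefficient(null, weighted = weighted_cp),
      lp = characteristic_path_length(null))
  })
  cp_null <- vapply(nulls, `[[`, numeric(1), "cp")
  lp_null <- vapply(nulls, `[[`, numeric(1), "lp")
  if (mean(cp_null) == 0 || mean(lp_null) == 0 || !is.finite(mean(lp_null))) {
    abort("null ensemble has degenerate mean Cp or Lp; normalization undefined",
          class = "wmnet_degenerate_null_error")
  }
  out <- tibble::tibble(
    gamma = cp_real / mean(cp_null),
    lambda = lp_real / mean(lp_null),
    sigma = (cp_real / mean(cp_null)) / (lp_real / mean(lp_null)),
    n_nulls = n_nulls
  )
  attr(out, "ensemble") <- tibble::tibble(null = seq_len(n_nulls),
                                          cp = cp_null, lp = lp_null)
  out
}
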