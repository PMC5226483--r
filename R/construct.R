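#' Subject connectivity data
#'
#' Bundles one participant's tractography outputs — the fiber-number (FN)
#' matrix, the mean fractional-anisotropy (FA) matrix per connection, and the
#' per-region volumes — together with group label, demographic covariates and
#' cognitive scores. FN counts streamlines between two parcellated regions;
#' FA is the mean anisotropy along those streamlines, a white-matter
#' integrity proxy in \[0, 1\].
#'
#' @param subject_id Character scalar.
#' @param group One of `"NC"`, `"SCD"`, `"aMCI"`.
#' @param fn Square symmetric matrix of non-negative streamline counts,
#'   zero diagonal.
#' @param fa Square symmetric matrix of per-connection mean FA in \[0, 1\],
#'   zero wherever `fn` is zero.
#' @param volumes Positive per-region volumes (mm^3), length matching `fn`.
#' @param age,education Years.
#' @param sex `"M"` or `"F"`.
#' @param scores Named numeric vector (e.g. MMSE, MoCA, AVLT_I, AVLT_D,
#'   AVLT_R); may be empty.
#' @param atlas A [region_atlas()]; defaults to [aal90_atlas()] when the
#'   matrices are 90 x 90.
#'
#' @return An object of class `subject_connectivity`.
#' @export
subject_connectivity <- function(subject_id, group, fn, fa, volumes,
                                 age = NA_real_, sex = NA_character_,
                                 education = NA_real_, scores = numeric(),
                                 atlas = NULL) {
  group <- match.arg(group, c("NC", "SCD", "aMCI"))
  if (!is_square_matrix(fn) || !is_square_matrix(fa)) {
    abort("fn and fa must be square numeric matrices", class = "wmnet_validation_error")
  }
  n <- nrow(fn)
  if (nrow(fa) != n || length(volumes) != n) {
    abort(sprintf(
      "dimension mismatch: fn is %d x %d, fa is %d x %d, volumes has length %d",
      n, n, nrow(fa), ncol(fa), length(volumes)
    ), class = "wmnet_dimension_error")
  }
  if (is.null(atlas)) {
    atlas <- if (n == 90) aal90_atlas() else
      region_atlas(sprintf("R%02d", seq_len(n)))
  }
  if (nrow(atlas) != n) {
    abort(sprintf("atlas has %d regions but matrices are %d x %d", nrow(atlas), n, n),
          class = "wmnet_dimension_error")
  }
  if (any(fn < 0)) {
    abort("fn contains negative streamline counts", class = "wmnet_validation_error")
  }
  if (any(fa < 0) || any(fa > 1)) {
    abort("fa entries must lie in [0, 1]", class = "wmnet_validation_error")
  }
  if (any(volumes <= 0)) {
    abort("region volumes must be positive", class = "wmnet_validation_error")
  }
  fn <- symmetrize(fn, what = "fn")
  fa <- symmetrize(fa, what = "fa")
  diag(fn) <- 0
  diag(fa) <- 0
  if (any(fa[fn == 0] != 0)) {
    abort("fa must be zero wherever fn is zero", class = "wmnet_validation_error")
  }
  structure(
    list(
      subject_id = as.character(subject_id), group = group,
      fn = fn, fa = fa, volumes = as.numeric(volumes),
      age = as.numeric(age), sex = as.character(sex),
      education = as.numeric(education),
      scores = scores, atlas = atlas
    ),
    class = "subject_connectivity"
  )
}

#' @export
print.subject_connectivity <- function(x, ...) {
  cat(sprintf(
    "<subject_connectivity> %s (%s): %d regions, %d suprathreshold-candidate edges\n",
    x$subject_id, x$group, nrow(x$fn), sum(x$fn[upper.tri(x$fn)] > 0)
  ))
  invisible(x)
}

#' Weighted structural network
#'
#' A symmetric, non-negative weight matrix with zero diagonal over an atlas.
#'
#' @param weights Square symmetric numeric matrix, finite, non-negative,
#'   zero diagonal.
#' @param atlas A [region_atlas()] matching the matrix dimension.
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, atlas = NULL) {
  if (!is_square_matrix(weights)) {
    abort("weights must be a square numeric matrix", class = "wmnet_validation_error")
  }
  n <- nrow(weights)
  if (is.null(atlas)) {
    atlas <- if (n == 90) aal90_atlas() else region_atlas(sprintf("R%02d", seq_len(n)))
  }
  if (nrow(atlas) != n) {
    abort("atlas dimension does not match weight matrix", class = "wmnet_dimension_error")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("weights must be finite and non-negative", class = "wmnet_validation_error")
  }
  weights <- symmetrize(weights, what = "weights")
  diag(weights) <- 0
  dimnames(weights) <- list(atlas$label, atlas$label)
  structure(list(weights = weights, atlas = atlas), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<weighted_network> %d nodes, %d edges, total weight %.4g\n",
              nrow(x$weights), m, sum(x$weights) / 2))
  invisible(x)
}

n_edges <- function(net) sum(net$weights[upper.tri(net$weights)] > 0)

#' Build the weighted network for one subject
#'
#' Two regions are connected when at least `fn_threshold` streamlines link
#' them (inclusive comparison); the connection weight is
#' `FN * FA / volume`, where `volume` is the arithmetic mean of the two
#' region volumes. Volume normalization offsets the tendency of larger
#' regions to accumulate spurious streamlines. Sub-threshold entries are set
#' to exactly zero.
#'
#' @param subject A [subject_connectivity()] object.
#' @param fn_threshold Minimum streamline count for an edge to exist
#'   (default 3).
#' @return A [weighted_network()].
#' @export
#' @examples
#' s <- generate_subject(cohort_spec(n_regions = 30), "NC", seed = 1)
#' net <- build_weight_matrix(s)
build_weight_matrix <- function(subject, fn_threshold = 3) {
  stopifnot(inherits(subject, "subject_connectivity"))
  if (!is.numeric(fn_threshold) || length(fn_threshold) != 1 || fn_threshold < 1) {
    abort("fn_threshold must be a single count >= 1", class = "wmnet_validation_error")
  }
  v <- subject$volumes
  mean_vol <- outer(v, v, function(a, b) (a + b) / 2)
  w <- subject$fn * subject$fa / mean_vol
  w[subject$fn < fn_threshold] <- 0
  diag(w) <- 0
  weighted_network(w, subject$atlas)
}

#' Edge stability across streamline thresholds
#'
#' Recomputes the network and its global metrics at each candidate
#' streamline threshold, the standard robustness check for the (arbitrary)
#' streamline cut-off. Raising the threshold can only remove edges.
#'
#' @param subject A [subject_connectivity()].
#' @param thresholds Integer vector of thresholds to scan (default `1:5`).
#' @param ... Passed to [global_metrics()] (e.g. `n_nulls`).
#' @return A tibble with one row per threshold: `fn_threshold`, `n_edges`,
#'   and the global metric columns.
#' @export
validate_threshold_stability <- function(subject, thresholds = 1:5, ...) {
  if (length(thresholds) == 0) {
    abort("thresholds must be non-empty", class = "wmnet_validation_error")
  }
  purrr::map_dfr(sort(thresholds), function(t) {
    net <- build_weight_matrix(subject, fn_threshold = t)
    dplyr::bind_cols(
      tibble::tibble(fn_threshold = t, n_edges = n_edges(net)),
      global_metrics(net, ...)
    )
  })
}
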