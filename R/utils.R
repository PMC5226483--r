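# Internal helpers shared across modules.

# Evaluate `code` with a locally-set RNG seed, restoring global RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive the per-draw seed for draw `i` from a master seed: a plain counter
# scheme so ensembles are reproducible draw-by-draw. Kept well below 2^31.
derive_seed <- function(master_seed, i) {
  s <- (as.double(master_seed) + 747796405 * as.double(i)) %% 2147483647
  as.integer(s)
}

is_square_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x)
}

# Symmetrize a nominally-symmetric matrix read from disk; asymmetry beyond
# `tol` (relative to the matrix scale) is an error, small asymmetry is
# averaged away.
symmetrize <- function(m, tol = 1e-8, what = "matrix") {
  d <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  if (d > tol * scale) {
    abort(sprintf("%s is asymmetric beyond tolerance (max |m - t(m)| = %.3g)", what, d),
          class = "wmnet_asymmetry_error")
  }
  (m + t(m)) / 2
}

upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}
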