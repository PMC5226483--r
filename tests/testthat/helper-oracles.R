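# Independent brute-force oracles for the graph metrics, deliberately naive:
# Floyd-Warshall for all-pairs path lengths and exhaustive simple-path
# enumeration for betweenness. Feasible for n <= 8.

# Edge-length matrix: 1/w, Inf where no edge.
length_matrix <- function(W) {
  L <- 1 / W
  L[W == 0] <- Inf
  diag(L) <- 0
  L
}

oracle_floyd_warshall <- function(W) {
  D <- length_matrix(W)
  n <- nrow(D)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Exhaustive betweenness: enumerate every simple path for each unordered
# pair, keep the minimal-length ones (relative tie tolerance), and credit
# interior nodes fractionally.
oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  B <- numeric(n)
  lenm <- length_matrix(W)
  for (j in seq_len(n - 1)) {
    for (k in seq(j + 1, n)) {
      env <- new.env()
      env$best <- Inf
      env$count <- 0
      env$through <- numeric(n)
      dfs <- function(cur, visited, len) {
        if (len > env$best * (1 + tol)) return(invisible())
        for (nxt in which(W[cur, ] > 0)) {
          if (visited[nxt]) next
          l2 <- len + lenm[cur, nxt]
          if (nxt == k) {
            if (l2 < env$best * (1 - tol)) {
              env$best <- l2
              env$count <- 1
              env$through <- as.numeric(visited); env$through[j] <- 0
            } else if (l2 <= env$best * (1 + tol)) {
              env$count <- env$count + 1
              add <- as.numeric(visited); add[j] <- 0
              env$through <- env$through + add
            }
          } else if (l2 <= env$best * (1 + tol)) {
            visited[nxt] <- TRUE
            dfs(nxt, visited, l2)
            visited[nxt] <- FALSE
          }
        }
      }
      v <- logical(n); v[j] <- TRUE
      dfs(j, v, 0)
      if (env$count > 0) B <- B + env$through / env$count
    }
  }
  B
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        if (W[nb[a], nb[b]] > 0) e <- e + 1
      }
    }
    ci[i] <- e / (k * (k - 1) / 2)
  }
  mean(ci)
}

oracle_global_eff <- function(W) {
  D <- oracle_floyd_warshall(W)
  n <- nrow(D)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(W) {
  n <- nrow(W)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) >= 2) e[i] <- oracle_global_eff(W[nb, nb, drop = FALSE])
  }
  mean(e)
}

# Random connected-ish toy weight matrix.
random_weights <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    on <- runif(length(up)) < p
    W[up[on]] <- runif(sum(on), 0.2, 2)
    W + t(W)
  })
}

toy_network <- function(W) {
  weighted_network(W, region_atlas(sprintf("N%02d", seq_len(nrow(W)))))
}

# Small synthetic subject with fully-controlled matrices.
toy_subject <- function(fn, fa, volumes, group = "NC", id = "t01") {
  subject_connectivity(id, group, fn, fa, volumes,
                       age = 60, sex = "F", education = 12,
                       atlas = region_atlas(sprintf("N%02d", seq_len(nrow(fn)))))
}

# Quick weight matrix for named graphs used across tests.
unit_complete <- function(n) {
  W <- matrix(1, n, n); diag(W) <- 0; W
}

ring_lattice_weights <- function(n, k, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in seq_len(k / 2)) {
      j <- ((i - 1 + d) %% n) + 1
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}
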