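# Independent brute-force oracles for the node measures, kept deliberately
# separate from the package implementation: plain BFS level expansion for
# distances, dynamic-programming shortest-path counting, and iterative
# peeling for coreness.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n)
    visited[s] <- TRUE
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0 & !visited)
      D[s, nxt] <- d
      visited[nxt] <- TRUE
      frontier <- nxt
    }
  }
  D
}

oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  for (s in seq_len(n)) {
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, preds])
    }
  }
  S
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) {
    return(numeric(n))
  }
  D <- oracle_distances(A)
  S <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (v in seq_len(n)) {
    through <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    frac <- outer(S[, v], S[v, ])
    contrib <- matrix(0, n, n)
    ok <- through & S > 0
    contrib[ok] <- frac[ok] / S[ok]
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    b[v] <- sum(contrib[upper.tri(contrib)]) / ((n - 1) * (n - 2) / 2)
  }
  b
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  if (n == 1) {
    return(0)
  }
  D <- oracle_distances(A)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    finite <- is.finite(d)
    r <- sum(finite) + 1
    s <- sum(d[finite])
    if (r == 1 || s == 0) 0 else (1 / s) * ((r - 1) / (n - 1))
  }, numeric(1))
}

oracle_coreness <- function(A) {
  A <- (A > 0) * 1
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0
  while (any(alive)) {
    k <- k + 1
    repeat {
      deg <- as.vector(A %*% alive)
      rm_now <- alive & deg < k
      if (!any(rm_now)) break
      core[rm_now] <- k - 1L
      alive[rm_now] <- FALSE
    }
  }
  core
}

oracle_degree <- function(A) {
  colSums(A > 0)
}

oracle_strength <- function(W) {
  colSums(W)
}

# Random symmetric hollow test graphs; weighted weights are positive uniforms.
random_graph <- function(n, p, seed, weighted = FALSE) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    pres <- stats::rbinom(sum(ut), 1, p)
    W[ut] <- if (weighted) pres * stats::runif(sum(ut), 0.1, 2) else pres
    W + t(W)
  })
}

# Small adjacency builders used across test files.
graph_from_edges <- function(n, edges, w = 1) {
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(edges))) {
    W[edges[e, 1], edges[e, 2]] <- W[edges[e, 2], edges[e, 1]] <- w
  }
  W
}

path_graph <- function(n) {
  graph_from_edges(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

star_graph <- function(n_leaves) {
  graph_from_edges(n_leaves + 1, cbind(1, seq_len(n_leaves) + 1))
}

complete_graph <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  W
}
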