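# The five node-level graph measures used for hub identification.
#
# Strength is computed on the weighted matrix; degree, coreness, betweenness
# and closeness are defined on the binarized (unit-weight) graph.

binary_graph <- function(W) {
  A <- (W > 0) * 1
  diag(A) <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Node degree and strength
#'
#' Degree counts the edges incident to a node (on the binarized graph);
#' strength sums the weights of those edges.
#'
#' @param matrix A symmetric, hollow, non-negative connectivity matrix.
#' @return A list with numeric vectors `degree` and `strength`, named by node.
#' @export
node_degree_strength <- function(matrix) {
  validate_matrix(matrix)
  ids <- node_ids(matrix)
  degree <- rowSums(matrix > 0)
  # 12-digit stabilization: symmetric nodes should tie exactly (see
  # node_betweenness)
  strength <- signif(rowSums(matrix), 12)
  names(degree) <- names(strength) <- ids
  list(degree = degree, strength = strength)
}

#' Node coreness (k-core decomposition)
#'
#' The coreness of a node is the largest k such that the node belongs to the
#' k-core: the maximal subgraph in which every node has at least k neighbours
#' within the subgraph. Computed on the binarized graph.
#'
#' @inheritParams node_degree_strength
#' @return Numeric vector of coreness values, named by node.
#' @export
node_coreness <- function(matrix) {
  validate_matrix(matrix)
  k <- igraph::coreness(binary_graph(matrix))
  names(k) <- node_ids(matrix)
  k
}

#' Node betweenness centrality
#'
#' The fraction of unweighted shortest paths between pairs of other nodes
#' that pass through the node: for node v, the mean over unordered pairs
#' (s, t) with s, t != v of sigma_st(v) / sigma_st, where sigma_st counts
#' shortest s-t paths and sigma_st(v) those with v in the interior. Pairs in
#' different components contribute 0. Normalised by the (n-1)(n-2)/2 eligible
#' pairs so the result lies in `[0, 1]`.
#'
#' @inheritParams node_degree_strength
#' @return Numeric vector of betweenness fractions in `[0, 1]`, named by node.
#' @export
node_betweenness <- function(matrix) {
  validate_matrix(matrix)
  n <- nrow(matrix)
  ids <- node_ids(matrix)
  if (n < 3) {
    b <- rep(0, n)
    names(b) <- ids
    return(b)
  }
  b <- igraph::betweenness(binary_graph(matrix), directed = FALSE, weights = NULL)
  b <- b / ((n - 1) * (n - 2) / 2)
  names(b) <- ids
  # stabilize to 12 significant digits so values that are exactly equal by
  # graph symmetry tie instead of being split by summation order
  signif(b, 12)
}

#' Node closeness centrality
#'
#' The reciprocal of the sum of unweighted shortest-path distances from the
#' node to all other nodes. On disconnected graphs the sum is taken over the
#' node's reachable set and the reciprocal is scaled by `(r - 1) / (n - 1)`
#' (Wasserman-Faust component scaling), where r is the reachable-set size
#' including the node itself; an isolated node has closeness 0. A warning is
#' emitted when the scaling is triggered, since the underlying definition
#' assumes a connected graph.
#'
#' @inheritParams node_degree_strength
#' @return Numeric vector of closeness values, named by node.
#' @export
node_closeness <- function(matrix) {
  validate_matrix(matrix)
  n <- nrow(matrix)
  ids <- node_ids(matrix)
  if (n == 1) {
    cl <- 0
    names(cl) <- ids
    return(cl)
  }
  D <- igraph::distances(binary_graph(matrix), weights = NA)
  cl <- numeric(n)
  disconnected <- FALSE
  for (v in seq_len(n)) {
    d <- D[v, -v]
    finite <- is.finite(d)
    if (!all(finite)) disconnected <- TRUE
    r <- sum(finite) + 1
    s <- sum(d[finite])
    cl[v] <- if (r == 1 || s == 0) 0 else (1 / s) * ((r - 1) / (n - 1))
  }
  if (disconnected) {
    rlang::warn("Graph is disconnected; closeness uses reachable-set scaling.")
  }
  names(cl) <- ids
  cl
}

#' All five node measures for one connectome
#'
#' Computes degree, strength, coreness, betweenness and closeness for every
#' node. Strength uses the edge weights; the other four are computed on the
#' binarized graph.
#'
#' @inheritParams node_degree_strength
#' @return A tibble with columns `node`, `degree`, `strength`, `coreness`,
#'   `betweenness`, `closeness`.
#' @examples
#' W <- matrix(0, 3, 3)
#' W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- W[1, 3] <- W[3, 1] <- 1
#' measure_all(W)
#' @export
measure_all <- function(matrix) {
  validate_matrix(matrix)
  ds <- node_degree_strength(matrix)
  tibble::tibble(
    node = node_ids(matrix),
    degree = unname(ds$degree),
    strength = unname(ds$strength),
    coreness = unname(node_coreness(matrix)),
    betweenness = unname(node_betweenness(matrix)),
    closeness = unname(suppressWarnings(node_closeness(matrix)))
  )
}
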