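# Building weighted and binary connectivity networks from streamline
# endpoint records.

#' Build a weighted connectivity matrix from streamline endpoints
#'
#' One record per streamline: its two endpoint ROIs and its length in mm.
#' For each unordered ROI pair (i, j) with at least one streamline, the edge
#' weight is
#'
#'     w_ij = n_ij * (1 / L_ij) * (2 / (V_i + V_j))
#'
#' where `n_ij` is the streamline count for the pair, `L_ij` their mean length
#' and `V_i`, `V_j` the endpoint ROI voxel counts. The `1 / L_ij` term
#' down-weights long fibers (deterministic tractography over-calls long
#' tracts); the `2 / (V_i + V_j)` term corrects residual ROI size differences.
#' Pairs without streamlines get weight 0. Records with both endpoints in the
#' same ROI are dropped: the network is hollow by construction.
#'
#' @param streamlines Data frame with columns `roi_a`, `roi_b`, `length_mm`
#'   (one row per streamline; lengths strictly positive).
#' @param roi_sizes Named numeric vector of per-ROI voxel counts; its names
#'   define the node index of the output matrix.
#' @return A symmetric, hollow connectivity matrix with ROI ids as dimnames.
#' @examples
#' sl <- data.frame(roi_a = "a", roi_b = "b", length_mm = 10)
#' build_weighted_matrix(sl, c(a = 400, b = 400)) # w_ab = 2.5e-4
#' @export
build_weighted_matrix <- function(streamlines, roi_sizes) {
  if (is.null(names(roi_sizes)) || any(!nzchar(names(roi_sizes)))) {
    abort_bad_arg("roi_sizes", "be a named vector (names are ROI ids)")
  }
  if (any(roi_sizes <= 0)) abort_bad_arg("roi_sizes", "have positive voxel counts")
  req <- c("roi_a", "roi_b", "length_mm")
  if (!all(req %in% names(streamlines))) {
    abort_bad_arg("streamlines", "have columns roi_a, roi_b, length_mm")
  }
  ids <- names(roi_sizes)
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(streamlines) == 0) {
    return(W)
  }
  if (any(streamlines$length_mm <= 0) || anyNA(streamlines$length_mm)) {
    abort_bad_arg("streamlines$length_mm", "be strictly positive")
  }
  ia <- match(as.character(streamlines$roi_a), ids)
  ib <- match(as.character(streamlines$roi_b), ids)
  if (anyNA(ia) || anyNA(ib)) {
    unknown <- unique(c(
      as.character(streamlines$roi_a)[is.na(ia)],
      as.character(streamlines$roi_b)[is.na(ib)]
    ))
    rlang::abort(
      sprintf("Unknown ROI id(s) in streamline table: %s.", paste(utils::head(unknown, 5), collapse = ", ")),
      class = "hubrank_error_index"
    )
  }
  keep <- ia != ib # intra-ROI streamlines carry no pairwise information
  if (!any(keep)) {
    return(W)
  }
  pairs <- tibble::tibble(
    i = pmin(ia[keep], ib[keep]),
    j = pmax(ia[keep], ib[keep]),
    length_mm = streamlines$length_mm[keep]
  ) |>
    dplyr::summarise(
      n_ij = dplyr::n(),
      mean_length = mean(.data$length_mm),
      .by = c("i", "j")
    )
  V <- as.numeric(roi_sizes)
  w <- pairs$n_ij * (1 / pairs$mean_length) * (2 / (V[pairs$i] + V[pairs$j]))
  W[cbind(pairs$i, pairs$j)] <- w
  W[cbind(pairs$j, pairs$i)] <- w
  W
}

#' Binarize a connectivity matrix
#'
#' Replaces every strictly positive weight with a unit weight; no threshold
#' is applied. Idempotent; the diagonal stays zero.
#'
#' @inheritParams node_degree_strength
#' @return A 0/1 matrix with the same dimnames.
#' @export
binarize <- function(matrix) {
  validate_matrix(matrix)
  B <- (matrix > 0) * 1
  diag(B) <- 0
  dimnames(B) <- dimnames(matrix)
  B
}
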