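# Synthetic atlas label volumes: compact, non-overlapping labelled regions
# with exact voxel counts, used as fixtures for sub-parcellation.

new_label_volume <- function(grid, voxel_size, labels) {
  structure(
    list(grid = grid, voxel_size = voxel_size, labels = labels),
    class = "label_volume"
  )
}

#' @exportS3Method base::print
print.label_volume <- function(x, ...) {
  cat(sprintf(
    "<label_volume> %s grid, %d parcels, %d labelled voxels\n",
    paste(dim(x$grid), collapse = "x"), nrow(x$labels), sum(x$grid > 0)
  ))
  invisible(x)
}

#' Generate a synthetic atlas label volume
#'
#' Places `n_parcels` spatially compact, non-overlapping labelled regions
#' with exactly the requested voxel counts into a 3D integer grid (background
#' label 0). Regions are trimmed Voronoi cells around randomly placed
#' centres: each cell keeps its voxels nearest to the centre, which keeps the
#' regions compact. Deterministic given `seed`.
#'
#' @param n_parcels Number of parcels.
#' @param voxels_per_parcel Integer vector of length `n_parcels` of requested
#'   voxel counts (all >= 1).
#' @param seed Integer RNG seed.
#' @param dims Optional grid dimensions (length 3); by default a cube sized to
#'   hold roughly three times the requested voxels. If supplied and the
#'   requested voxels exceed `prod(dims)`, a capacity error is raised.
#' @param voxel_size Edge lengths of a voxel in mm (length 3).
#' @param hemisphere,homolog Optional per-parcel metadata vectors recorded in
#'   the label table (hemisphere codes and homolog label ids).
#' @return A `label_volume`: list with the integer `grid`, `voxel_size`, and a
#'   `labels` tibble (label, name, hemisphere, homolog).
#' @export
generate_label_volume <- function(n_parcels, voxels_per_parcel, seed = 1L,
                                  dims = NULL, voxel_size = c(1, 1, 1),
                                  hemisphere = NULL, homolog = NULL) {
  n_parcels <- check_count(n_parcels, "n_parcels")
  v <- as.integer(voxels_per_parcel)
  if (length(v) != n_parcels || any(is.na(v)) || any(v < 1)) {
    abort_bad_arg("voxels_per_parcel", sprintf("be %d positive integer counts", n_parcels))
  }
  total <- sum(v)
  if (!is.null(dims)) {
    if (length(dims) != 3 || any(dims < 1)) abort_bad_arg("dims", "be three positive integers")
    if (total > prod(dims)) {
      rlang::abort(
        sprintf(
          "Requested %d voxels exceed grid capacity %d.",
          total, prod(dims)
        ),
        class = "hubrank_error_capacity"
      )
    }
  } else {
    side <- max(4, ceiling((3 * total)^(1 / 3)))
    dims <- c(side, side, side)
  }
  dims <- as.integer(dims)
  nvox <- prod(dims)
  coords <- as.matrix(expand.grid(
    x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3])
  ))

  grid <- with_seed(seed, {
    ord_req <- order(v, decreasing = TRUE)
    g <- NULL
    for (attempt in 1:50) {
      centers <- coords[sample.int(nvox, n_parcels), , drop = FALSE]
      D2 <- outer(rowSums(coords^2), rep(1, n_parcels)) -
        2 * coords %*% t(centers) +
        outer(rep(1, nvox), rowSums(centers^2))
      cell <- max.col(-D2, ties.method = "first")
      cell_sizes <- tabulate(cell, nbins = n_parcels)
      ord_cell <- order(cell_sizes, decreasing = TRUE)
      if (all(cell_sizes[ord_cell] >= v[ord_req])) {
        g <- array(0L, dim = dims)
        for (t in seq_len(n_parcels)) {
          lab <- ord_req[t]
          cl <- ord_cell[t]
          members <- which(cell == cl)
          keep <- members[order(D2[members, cl])][seq_len(v[lab])]
          g[keep] <- lab
        }
        break
      }
    }
    if (is.null(g)) {
      rlang::abort(
        "Could not place all parcels with the requested sizes; enlarge `dims`.",
        class = "hubrank_error_capacity"
      )
    }
    g
  })

  labels <- tibble::tibble(
    label = seq_len(n_parcels),
    name = sprintf("parcel_%03d", seq_len(n_parcels)),
    hemisphere = if (is.null(hemisphere)) NA_character_ else as.character(hemisphere),
    homolog = if (is.null(homolog)) NA_integer_ else as.integer(homolog)
  )
  new_label_volume(grid, as.numeric(voxel_size), labels)
}

#' Generate a streamline endpoint table from a connectivity matrix
#'
#' Inverts the edge-weight formula: for every edge (i, j) a per-pair mean
#' length `L_ij` is drawn uniformly from `length_range` and the streamline
#' count is set to `n_ij = round(w_ij * L_ij * (V_i + V_j) / 2)`, so that
#' rebuilding the matrix with [build_weighted_matrix()] recovers the input up
#' to integer rounding of the counts. Individual streamline lengths are
#' jittered around `L_ij` and recentred so their mean equals `L_ij` exactly.
#'
#' @param matrix A connectivity matrix (symmetric, hollow, non-negative).
#' @param roi_sizes Named per-node voxel counts covering the matrix nodes.
#' @param length_range Length 2: min and max per-pair mean length in mm.
#' @param seed Integer RNG seed.
#' @return A tibble with one row per streamline: `roi_a`, `roi_b`,
#'   `length_mm`.
#' @export
generate_streamlines <- function(matrix, roi_sizes, length_range = c(30, 300),
                                 seed = 1L) {
  validate_matrix(matrix)
  ids <- node_ids(matrix)
  if (is.null(names(roi_sizes)) || !all(ids %in% names(roi_sizes))) {
    abort_bad_arg("roi_sizes", "be named and cover every matrix node")
  }
  if (length(length_range) != 2 || any(length_range <= 0) ||
    length_range[1] > length_range[2]) {
    abort_bad_arg("length_range", "be two positive increasing lengths in mm")
  }
  V <- as.numeric(roi_sizes[ids])
  ut <- which(upper.tri(matrix) & matrix > 0, arr.ind = TRUE)
  empty <- tibble::tibble(
    roi_a = character(0), roi_b = character(0), length_mm = numeric(0)
  )
  if (nrow(ut) == 0) {
    return(empty)
  }
  with_seed(seed, {
    w <- matrix[ut]
    L <- stats::runif(nrow(ut), length_range[1], length_range[2])
    n_ij <- round(w * L * (V[ut[, 1]] + V[ut[, 2]]) / 2)
    keep <- n_ij >= 1
    if (!any(keep)) {
      empty
    } else {
      ut <- ut[keep, , drop = FALSE]
      L <- L[keep]
      n_ij <- n_ij[keep]
      idx <- rep(seq_along(n_ij), n_ij)
      jitter <- stats::runif(length(idx), 0.9, 1.1)
      # recentre the jitter per pair so the recorded mean length is exactly L
      mul <- jitter - stats::ave(jitter, idx) + 1
      tibble::tibble(
        roi_a = ids[ut[idx, 1]],
        roi_b = ids[ut[idx, 2]],
        length_mm = mul * L[idx]
      )
    }
  })
}
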