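# Atlas sub-parcellation: split parcels into similar-size, spatially compact
# ROIs by k-means clustering of voxel coordinates.

#' Number of ROIs for a parcel
#'
#' The integer quotient of the parcel's voxel count by `target_size`
#' (default 400 voxels). Parcels smaller than the target are not split and
#' yield a single ROI. For example a 3,000-voxel parcel yields k = 7.
#'
#' @param n_voxels Voxel count of the parcel (>= 1).
#' @param target_size Target ROI size in voxels (>= 1).
#' @return Integer number of clusters k (>= 1).
#' @examples
#' determine_k(3000) # 7
#' determine_k(399) # 1
#' @export
determine_k <- function(n_voxels, target_size = 400) {
  n_voxels <- check_count(n_voxels, "n_voxels")
  target_size <- check_count(target_size, "target_size")
  if (n_voxels < target_size) {
    return(1L)
  }
  as.integer(n_voxels %/% target_size)
}

kmeans_pp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  if (k > 1) {
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = d2)
      }
      dj <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
  }
  X[centers, , drop = FALSE]
}

lloyd_once <- function(X, k, iter_max) {
  n <- nrow(X)
  C <- kmeans_pp_centers(X, k)
  assign_prev <- rep(0L, n)
  for (iter in seq_len(iter_max)) {
    D2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
    assignment <- max.col(-D2, ties.method = "first")
    # empty clusters: reseed the centroid at the voxel farthest from its
    # current centre
    empties <- which(tabulate(assignment, nbins = k) == 0)
    if (length(empties) > 0) {
      dcur <- D2[cbind(seq_len(n), assignment)]
      for (j in empties) {
        far <- which.max(dcur)
        assignment[far] <- j
        dcur[far] <- -Inf
      }
    }
    if (identical(assignment, assign_prev)) break
    assign_prev <- assignment
    C <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(X[assignment == j, , drop = FALSE])
    }))
  }
  wss <- sum((X - C[assignment, , drop = FALSE])^2)
  list(assignment = assignment, objective = wss / n)
}

#' Sub-parcellate one parcel by k-means on voxel coordinates
#'
#' Clusters the parcel's voxel coordinates into k spatially compact groups by
#' Lloyd's k-means with k-means++ initialisation, squared-Euclidean
#' objective, `n_restarts` restarts and an iteration cap; the best restart by
#' mean within-cluster squared distance is kept. Deterministic given `seed`.
#'
#' @param voxel_coords Numeric matrix of voxel coordinates (rows = voxels,
#'   columns = axes, in mm).
#' @param k Number of clusters (1 <= k <= number of voxels).
#' @param seed Integer RNG seed.
#' @param n_restarts Number of k-means restarts (default 10).
#' @param iter_max Iteration cap per restart (default 300).
#' @return Integer vector of per-voxel cluster labels in 1..k, with the
#'   achieved objective (mean within-cluster squared distance) as attribute
#'   `objective`.
#' @export
subparcellate_parcel <- function(voxel_coords, k, seed = 1L,
                                 n_restarts = 10, iter_max = 300) {
  X <- as.matrix(voxel_coords)
  storage.mode(X) <- "double"
  k <- check_count(k, "k")
  if (k > nrow(X)) {
    rlang::abort(
      sprintf("k = %d exceeds the parcel's %d voxels.", k, nrow(X)),
      class = "hubrank_error_infeasible"
    )
  }
  if (k == 1) {
    out <- rep(1L, nrow(X))
    attr(out, "objective") <- sum(scale(X, scale = FALSE)^2) / nrow(X)
    return(out)
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(X, k, iter_max)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    out <- as.integer(best$assignment)
    attr(out, "objective") <- best$objective
    out
  })
}

roi_connected_components <- function(ind) {
  # 6-connectivity flood fill over voxel index triples
  key <- paste(ind[, 1], ind[, 2], ind[, 3], sep = ",")
  comp <- rep(0L, nrow(ind))
  shifts <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  current <- 0L
  for (start in seq_len(nrow(ind))) {
    if (comp[start] != 0L) next
    current <- current + 1L
    frontier <- start
    comp[start] <- current
    while (length(frontier) > 0) {
      nbr_keys <- unlist(lapply(frontier, function(f) {
        paste(ind[f, 1] + shifts[, 1], ind[f, 2] + shifts[, 2],
          ind[f, 3] + shifts[, 3],
          sep = ","
        )
      }))
      hits <- match(unique(nbr_keys), key)
      hits <- hits[!is.na(hits)]
      frontier <- hits[comp[hits] == 0L]
      comp[frontier] <- current
    }
  }
  max(comp)
}

#' Sub-parcellate an atlas label volume
#'
#' Applies [determine_k()] and [subparcellate_parcel()] to every parcel of a
#' label volume. ROI ids are assigned in parcel order then cluster order;
#' voxel counts are conserved (every labelled voxel lands in exactly one
#' ROI). Each ROI is audited for spatial contiguity (6-connectivity); a
#' non-contiguous ROI triggers a warning, not an error, since k-means does
#' not formally enforce contiguity on non-convex parcels.
#'
#' @param volume A `label_volume` (see [generate_label_volume()] and
#'   [read_label_volume()]).
#' @param target_size Target ROI size in voxels (default 400).
#' @param seed Integer RNG seed; per-parcel sub-seeds are derived from it.
#' @param audit_contiguity If `TRUE` (default), warn about non-contiguous
#'   ROIs.
#' @return A list with `map` (tibble: roi_id, parcel, parcel_name,
#'   hemisphere, homolog_parcel, n_voxels, centroid_x/y/z) and `volume` (a
#'   `label_volume` relabelled with ROI ids).
#' @export
subparcellate_atlas <- function(volume, target_size = 400, seed = 1L,
                                audit_contiguity = TRUE) {
  if (!inherits(volume, "label_volume")) {
    abort_bad_arg("volume", "be a label_volume")
  }
  grid <- volume$grid
  vsz <- volume$voxel_size
  labs <- sort(unique(as.integer(grid[grid > 0])))
  meta <- volume$labels
  if (!all(labs %in% meta$label)) {
    missing_lab <- setdiff(labs, meta$label)
    rlang::abort(
      sprintf(
        "Label(s) %s present in the grid but absent from the metadata table.",
        paste(missing_lab, collapse = ", ")
      ),
      class = "hubrank_error_validation"
    )
  }
  parcel_seeds <- derive_seeds(seed, length(labs))
  roi_grid <- array(0L, dim = dim(grid))
  rows <- list()
  roi_id <- 0L
  noncontiguous <- character(0)
  for (li in seq_along(labs)) {
    lab <- labs[li]
    ind <- which(grid == lab, arr.ind = TRUE)
    coords <- sweep(ind - 0.5, 2, vsz, `*`)
    k <- determine_k(nrow(ind), target_size)
    cl <- subparcellate_parcel(coords, k, seed = parcel_seeds[li])
    mrow <- meta[meta$label == lab, ]
    for (j in seq_len(k)) {
      roi_id <- roi_id + 1L
      sel <- cl == j
      roi_grid[ind[sel, , drop = FALSE]] <- roi_id
      cen <- colMeans(coords[sel, , drop = FALSE])
      rows[[roi_id]] <- tibble::tibble(
        roi_id = roi_id,
        parcel = lab,
        parcel_name = mrow$name %||% NA_character_,
        hemisphere = mrow$hemisphere %||% NA_character_,
        homolog_parcel = mrow$homolog %||% NA_integer_,
        n_voxels = sum(sel),
        centroid_x = cen[1], centroid_y = cen[2], centroid_z = cen[3]
      )
      if (audit_contiguity && sum(sel) > 1 &&
        roi_connected_components(ind[sel, , drop = FALSE]) > 1) {
        noncontiguous <- c(noncontiguous, as.character(roi_id))
      }
    }
  }
  if (length(noncontiguous) > 0) {
    rlang::warn(sprintf(
      "ROI(s) %s are not spatially contiguous (6-connectivity audit).",
      paste(noncontiguous, collapse = ", ")
    ))
  }
  map <- dplyr::bind_rows(rows)
  list(
    map = map,
    volume = new_label_volume(
      roi_grid, vsz,
      tibble::tibble(
        label = map$roi_id,
        name = sprintf("%s_roi%02d", map$parcel_name, stats::ave(
          map$roi_id, map$parcel,
          FUN = seq_along
        )),
        hemisphere = map$hemisphere,
        homolog = NA_integer_
      )
    )
  )
}
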