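# Downstream group-level experiments: sample-size curves, consistent-hub
# sets, hemispheric asymmetry of homologous parcels, and intraparcel
# heterogeneity of hubness ranks.

#' Sample-size curve of representation power
#'
#' For each sample size, repeatedly draws a random sample of subjects
#' (without replacement within a replicate, independently across replicates),
#' computes the sample-averaged MTA hubness ranking, and correlates it
#' (Spearman) with the full-population MTA hubness ranking. The curve shows
#' how many subjects are needed before the sample ranking stabilises at the
#' population ranking.
#'
#' @inheritParams aggregate_mta
#' @param sizes Integer vector of sample sizes; each must not exceed the
#'   population size.
#' @param n_replicates Replicates per size (default 100).
#' @param seed Integer RNG seed.
#' @return A `sample_size_curve` tibble with columns `size`, `replicate`,
#'   `correlation`; per-size mean and range via [glance()].
#' @export
sample_size_curve <- function(pop, sizes = c(1, 2, 5, 10, 20, 50, 100),
                              n_replicates = 100, seed = 1L, ranks = NULL) {
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  n_subj <- dim(ranks)[3]
  sizes <- vapply(sizes, check_count, integer(1), arg = "sizes")
  if (any(sizes > n_subj)) {
    abort_bad_arg("sizes", sprintf("not exceed the population size (%d)", n_subj))
  }
  n_replicates <- check_count(n_replicates, "n_replicates")
  H <- ranks[, "hubness", , drop = TRUE]
  if (is.null(dim(H))) H <- matrix(H, ncol = n_subj)
  ref <- rowMeans(H)
  res <- with_seed(seed, {
    purrr::map(sizes, function(ns) {
      cors <- vapply(seq_len(n_replicates), function(r) {
        idx <- sample.int(n_subj, ns)
        spearman_rank(rowMeans(H[, idx, drop = FALSE]), ref)
      }, numeric(1))
      tibble::tibble(size = ns, replicate = seq_len(n_replicates), correlation = cors)
    })
  })
  structure(
    dplyr::bind_rows(res),
    n_subjects = n_subj, seed = seed,
    class = c("sample_size_curve", class(tibble::tibble()))
  )
}

#' Consistently top-ranked hub nodes
#'
#' Identifies the nodes whose MTA group rank score is within the best
#' `quantile` fraction for every one of the five node measures (the
#' intersection of the five top sets). Top sets contain the
#' `floor(quantile * n)` best-scoring nodes; ties at the cutoff are broken by
#' node order, which makes the hub set monotone in `quantile`.
#'
#' @inheritParams aggregate_mta
#' @param quantile Fraction of top-ranked nodes per measure (default 0.20).
#' @return A `hub_set` list with `hubs` (node ids), `by_hemisphere` (tibble
#'   of per-hemisphere counts when hemisphere metadata is available) and
#'   `per_measure` (the five top sets).
#' @export
top_consistent_hubs <- function(pop, quantile = 0.20, ranks = NULL) {
  quantile <- check_fraction(quantile, "quantile")
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  ids <- dimnames(ranks)[[1]]
  n <- length(ids)
  m_top <- floor(quantile * n + 1e-9)
  per_measure <- lapply(MEASURE_NAMES, function(m) {
    score <- rowMeans(ranks[, m, , drop = FALSE], dims = 1)
    ids[order(score, seq_len(n))[seq_len(m_top)]]
  })
  names(per_measure) <- MEASURE_NAMES
  hubs <- Reduce(intersect, per_measure)
  info <- if (is.null(pop)) tibble::tibble(node = ids) else pop_node_info(pop)
  by_hemisphere <- if ("hemisphere" %in% names(info) && !all(is.na(info$hemisphere))) {
    dplyr::count(
      dplyr::filter(info, .data$node %in% hubs),
      .data$hemisphere,
      name = "n_hubs"
    )
  } else {
    tibble::tibble(hemisphere = NA_character_, n_hubs = length(hubs))
  }
  structure(
    list(hubs = hubs, by_hemisphere = by_hemisphere, per_measure = per_measure),
    quantile = quantile, n_nodes = n,
    class = "hub_set"
  )
}

#' @exportS3Method base::print
print.hub_set <- function(x, ...) {
  cat(sprintf(
    "<hub_set> %d nodes in the top %.0f%% of all five measures\n",
    length(x$hubs), 100 * attr(x, "quantile")
  ))
  print(x$by_hemisphere)
  invisible(x)
}

#' Per-subject parcel-level median ROI ranks
#'
#' ROIs produced by sub-parcellation are not homologous across hemispheres,
#' so hemispheric comparisons are done at the parcel level: for each subject,
#' a parcel's value is the median of its ROIs' within-subject hubness ranks
#' (even ROI counts use the midpoint of the two central ranks).
#'
#' @inheritParams aggregate_mta
#' @param map Node metadata: a tibble with columns `node`, `parcel` and
#'   (optionally) `hemisphere`, `homolog_parcel`; defaults to the
#'   population's own `node_info`.
#' @return A tibble with columns `subject`, `parcel`, `hemisphere`,
#'   `median_rank`. Attributes `n_nodes` (total ranked nodes, the rank unit
#'   scale) and `homolog_pairs` (tibble of left/right parcel ids, when
#'   derivable) feed [hemispheric_asymmetry()].
#' @export
parcel_rank_table <- function(pop, map = NULL, ranks = NULL) {
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  if (is.null(map) && !is.null(pop)) map <- pop_node_info(pop)
  if (is.null(map)) abort_bad_arg("map", "be supplied when `pop` is NULL")
  ids <- dimnames(ranks)[[1]]
  if (!all(ids %in% map$node)) {
    abort_bad_arg("map", "cover every node in the population")
  }
  if (!"parcel" %in% names(map) || anyNA(map$parcel[match(ids, map$node)])) {
    rlang::abort(
      "Every node needs a parcel assignment in `map`.",
      class = "hubrank_error_validation"
    )
  }
  H <- ranks[, "hubness", , drop = TRUE]
  if (is.null(dim(H))) H <- matrix(H, ncol = dim(ranks)[3])
  n_subj <- ncol(H)
  long <- tidyr::expand_grid(subject = seq_len(n_subj), node = ids) |>
    dplyr::mutate(rank = as.numeric(H[cbind(
      match(.data$node, ids),
      .data$subject
    )])) |>
    dplyr::left_join(map[, intersect(c("node", "parcel", "hemisphere"), names(map))],
      by = "node"
    )
  if (!"hemisphere" %in% names(long)) long$hemisphere <- NA_character_
  out <- long |>
    dplyr::summarise(
      median_rank = stats::median(.data$rank),
      .by = c("subject", "parcel", "hemisphere")
    )
  pairs <- NULL
  if (all(c("hemisphere", "homolog_parcel") %in% names(map))) {
    pairs <- map |>
      dplyr::filter(.data$hemisphere == "L") |>
      dplyr::distinct(.data$parcel, .data$homolog_parcel) |>
      dplyr::rename(parcel_left = "parcel", parcel_right = "homolog_parcel")
  }
  structure(out,
    n_nodes = length(ids), homolog_pairs = pairs,
    class = c("parcel_rank_table", class(tibble::tibble()))
  )
}

#' Hemispheric asymmetry of homologous parcels
#'
#' For each homologous left/right parcel pair, the per-subject paired
#' differences of median ROI hubness ranks (left minus right) are tested with
#' a two-sided paired test (Wilcoxon signed-rank by default, exact for small
#' samples without ties; a paired t-test is available). A pair is classified
#' dominant on the side with the better (lower) ranks iff the p-value is
#' below `alpha` *and* the absolute mean difference exceeds
#' `margin * n_units` rank units — the margin expresses an "acceptable
#' difference" of 5% of the ranked units by default. Otherwise the pair is
#' symmetric.
#'
#' @param table A [parcel_rank_table()] result.
#' @param pairs Tibble with columns `parcel_left`, `parcel_right`; defaults
#'   to the pairing carried by `table`.
#' @param margin Fraction of the total ranked units used as the acceptable
#'   difference (default 0.05).
#' @param alpha Significance level (default 0.01).
#' @param n_units Total number of ranked units (defaults to the node count
#'   carried by `table`).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param adjust Multiple-testing correction passed to [stats::p.adjust()];
#'   `"none"` by default (raw p-values, as is conventional for this margin +
#'   alpha rule), `"BH"` available.
#' @return An `asymmetry_report` tibble: one row per pair with `mean_diff`
#'   (left - right, rank units), `p_value`, `classification` in
#'   left-dominant / right-dominant / symmetric. Class counts via [glance()].
#' @export
hemispheric_asymmetry <- function(table, pairs = NULL, margin = 0.05,
                                  alpha = 0.01, n_units = NULL,
                                  test = c("wilcoxon", "t"),
                                  adjust = "none") {
  test <- match.arg(test)
  margin <- check_fraction(margin, "margin")
  alpha <- check_fraction(alpha, "alpha", lo_open = TRUE)
  if (is.null(pairs)) pairs <- attr(table, "homolog_pairs")
  if (is.null(pairs) || !all(c("parcel_left", "parcel_right") %in% names(pairs))) {
    abort_bad_arg("pairs", "be a tibble with columns parcel_left, parcel_right")
  }
  if (is.null(n_units)) n_units <- attr(table, "n_nodes")
  if (is.null(n_units)) abort_bad_arg("n_units", "be supplied (total ranked units)")
  n_subj <- length(unique(table$subject))
  if (n_subj < 6) {
    abort_bad_arg("table", "contain at least 6 subjects for the paired test")
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    pl <- pairs$parcel_left[i]
    pr <- pairs$parcel_right[i]
    tl <- table[table$parcel == pl, ]
    tr <- table[table$parcel == pr, ]
    if (nrow(tl) != n_subj || nrow(tr) != n_subj) {
      skipped <- c(skipped, sprintf("%s/%s", pl, pr))
      next
    }
    d <- tl$median_rank[order(tl$subject)] - tr$median_rank[order(tr$subject)]
    p <- if (all(d == 0)) {
      1
    } else if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(d)$p.value)
    } else {
      stats::t.test(d)$p.value
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      parcel_left = pl, parcel_right = pr,
      mean_diff = mean(d), p_value = p
    )
  }
  if (length(skipped) > 0) {
    rlang::warn(sprintf(
      "Skipped unpaired/incomplete parcel pair(s): %s.",
      paste(skipped, collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$classification <- ifelse(
    out$p_value < alpha & abs(out$mean_diff) > margin * n_units,
    ifelse(out$mean_diff < 0, "left-dominant", "right-dominant"),
    "symmetric"
  )
  lv <- c("left-dominant", "right-dominant", "symmetric")
  counts <- lapply(stats::setNames(lv, lv), function(l) sum(out$classification == l))
  structure(out,
    class_counts = counts,
    margin = margin, alpha = alpha, n_units = n_units, test = test,
    class = c("asymmetry_report", class(tibble::tibble()))
  )
}

#' Group-level parcel median ranks per hemisphere
#'
#' Converts a group ranking's scores into group-level node ranks (rank 1 =
#' most hub-like) and takes each parcel's median over its ROIs.
#'
#' @param group A `group_ranking` (typically MTA hubness).
#' @param map Node metadata tibble with `node`, `parcel`, `hemisphere`.
#' @return Tibble with columns `parcel`, `hemisphere`, `median_rank`.
#' @export
group_parcel_ranks <- function(group, map) {
  if (!all(group$node %in% map$node)) {
    abort_bad_arg("map", "cover every node in the group ranking")
  }
  group_rank <- rank_vector(group$score, descending = FALSE)
  tibble::tibble(
    node = group$node,
    rank = as.numeric(group_rank)
  ) |>
    dplyr::left_join(map[, intersect(c("node", "parcel", "hemisphere"), names(map))],
      by = "node"
    ) |>
    dplyr::summarise(
      median_rank = stats::median(.data$rank),
      .by = c("parcel", "hemisphere")
    )
}

#' Interhemispheric correlation of parcel ranks
#'
#' Spearman correlation between the left and right group-level parcel median
#' rank vectors, aligned by homologous pair.
#'
#' @param left,right Numeric vectors of parcel median ranks, aligned so that
#'   element i of `left` is homologous to element i of `right`.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
interhemispheric_correlation <- function(left, right) {
  spearman_rank(left, right)
}

#' Intraparcel heterogeneity of group-level hubness ranks
#'
#' Summarises, per parcel, the spread of the group-level hubness ranks of its
#' ROIs (minimum, maximum, median, interquartile range). Single-ROI parcels
#' have zero spread by construction. Optionally correlates each homologous
#' pair's median rank with its asymmetry magnitude to check whether more
#' hub-like parcels are more or less asymmetric.
#'
#' @param group A `group_ranking` (typically MTA hubness).
#' @param map Node metadata tibble with `node`, `parcel` (and `hemisphere`
#'   for the asymmetry correlation).
#' @param asymmetry Optional [hemispheric_asymmetry()] report; when given,
#'   the Spearman correlation between pair median rank and `|mean_diff|` is
#'   stored as attribute `rank_asymmetry_correlation`.
#' @return A `heterogeneity_report` tibble: one row per parcel with `n_rois`,
#'   `min_rank`, `max_rank`, `median_rank`, `iqr`. The ROI-level ranks are
#'   kept in attribute `roi_ranks` for plotting.
#' @export
intraparcel_heterogeneity <- function(group, map, asymmetry = NULL) {
  if (!all(group$node %in% map$node)) {
    abort_bad_arg("map", "cover every node in the group ranking")
  }
  roi <- tibble::tibble(
    node = group$node,
    rank = as.numeric(rank_vector(group$score, descending = FALSE))
  ) |>
    dplyr::left_join(map[, intersect(c("node", "parcel", "hemisphere"), names(map))],
      by = "node"
    )
  out <- roi |>
    dplyr::summarise(
      n_rois = dplyr::n(),
      min_rank = min(.data$rank),
      max_rank = max(.data$rank),
      median_rank = stats::median(.data$rank),
      iqr = stats::IQR(.data$rank),
      .by = "parcel"
    )
  rank_asym_cor <- NA_real_
  if (!is.null(asymmetry)) {
    pair_stats <- asymmetry |>
      tibble::as_tibble() |>
      dplyr::left_join(
        dplyr::rename(out[, c("parcel", "median_rank")], left_rank = "median_rank"),
        by = c("parcel_left" = "parcel")
      ) |>
      dplyr::left_join(
        dplyr::rename(out[, c("parcel", "median_rank")], right_rank = "median_rank"),
        by = c("parcel_right" = "parcel")
      ) |>
      dplyr::mutate(
        pair_rank = (.data$left_rank + .data$right_rank) / 2,
        magnitude = abs(.data$mean_diff)
      )
    if (nrow(pair_stats) >= 2) {
      rank_asym_cor <- spearman_rank(pair_stats$pair_rank, pair_stats$magnitude)
    }
  }
  structure(out,
    roi_ranks = roi, rank_asymmetry_correlation = rank_asym_cor,
    class = c("heterogeneity_report", class(tibble::tibble()))
  )
}
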