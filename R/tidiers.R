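# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group ranking
#'
#' @param x A `group_ranking`.
#' @param ... Unused.
#' @return Tibble with `node`, `score`, `rank` (the ranking of the scores,
#'   1 = most hub-like), `method`, `measure`.
#' @export
tidy.group_ranking <- function(x, ...) {
  tibble::tibble(
    node = x$node,
    score = x$score,
    rank = as.numeric(rank_vector(x$score, descending = FALSE)),
    method = attr(x, "method"),
    measure = attr(x, "measure")
  )
}

#' @rdname tidy.group_ranking
#' @export
glance.group_ranking <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    measure = attr(x, "measure"),
    n_nodes = nrow(x)
  )
}

#' Tidy / summarise representation power
#'
#' @param x A `representation_power` object.
#' @param ... Unused.
#' @export
tidy.representation_power <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.representation_power
#' @export
glance.representation_power <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    measure = attr(x, "measure"),
    n_subjects = nrow(x),
    mean_correlation = attr(x, "mean_correlation")
  )
}

#' Summarise an aggregation comparison
#'
#' @param x An `aggregation_comparison`.
#' @param ... Unused.
#' @return One row per measure-method pair with the mean representation
#'   correlation.
#' @export
glance.aggregation_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::summarise(
      mean_correlation = mean(.data$correlation),
      .by = c("measure", "method")
    )
}

#' Summarise a sample-size curve
#'
#' @param x A `sample_size_curve`.
#' @param ... Unused.
#' @return One row per sample size with mean, minimum and maximum replicate
#'   correlation.
#' @export
glance.sample_size_curve <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::summarise(
      mean_correlation = mean(.data$correlation),
      min_correlation = min(.data$correlation),
      max_correlation = max(.data$correlation),
      .by = "size"
    ) |>
    dplyr::arrange(.data$size)
}

#' Summarise an asymmetry report
#'
#' @param x An `asymmetry_report`.
#' @param ... Unused.
#' @return One row with the class counts and the test configuration.
#' @export
glance.asymmetry_report <- function(x, ...) {
  cc <- attr(x, "class_counts")
  tibble::tibble(
    n_pairs = nrow(x),
    left_dominant = cc[["left-dominant"]],
    right_dominant = cc[["right-dominant"]],
    symmetric = cc[["symmetric"]],
    margin = attr(x, "margin"),
    alpha = attr(x, "alpha"),
    test = attr(x, "test")
  )
}

#' Summarise a heterogeneity report
#'
#' @param x A `heterogeneity_report`.
#' @param ... Unused.
#' @return One row with parcel counts, the mean IQR, and the correlation
#'   between pair median rank and asymmetry magnitude (NA when no asymmetry
#'   report was supplied).
#' @export
glance.heterogeneity_report <- function(x, ...) {
  tibble::tibble(
    n_parcels = nrow(x),
    n_multi_roi = sum(x$n_rois > 1),
    mean_iqr = mean(x$iqr),
    rank_asymmetry_correlation = attr(x, "rank_asymmetry_correlation")
  )
}
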