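# Ranking vectors, Spearman rank correlation, and the composite hubness score.

#' Rank nodes by a measure
#'
#' Converts per-node measure values into a ranking vector where rank 1 is the
#' top node. With `descending = TRUE` (the default) the largest value receives
#' rank 1, which is the convention for all five hub measures: a high degree,
#' strength, coreness, betweenness or closeness makes a node more hub-like.
#' Ties receive the average of the ranks they span (fractional ranks), so the
#' ranks always sum to `n(n+1)/2`.
#'
#' For example, degree values `c(50, 20, 30, 40, 10)` yield the ranking vector
#' `c(1, 4, 3, 2, 5)`: the first node is the top-ranking node.
#'
#' @param values Numeric vector of per-node measure values (no missing values).
#' @param descending If `TRUE`, the largest value gets rank 1; if `FALSE`, the
#'   smallest (used for composite scores where lower means more hub-like).
#' @return Numeric vector of ranks, named like `values`.
#' @examples
#' rank_vector(c(50, 20, 30, 40, 10))
#' @export
rank_vector <- function(values, descending = TRUE) {
  if (length(values) == 0) abort_bad_arg("values", "be non-empty")
  if (!is.numeric(values)) abort_bad_arg("values", "be numeric")
  if (anyNA(values)) abort_bad_arg("values", "not contain missing values")
  r <- if (descending) {
    rank(-values, ties.method = "average")
  } else {
    rank(values, ties.method = "average")
  }
  names(r) <- names(values)
  r
}

#' Spearman rank correlation between two rankings
#'
#' For tie-free rankings this evaluates the classical closed form
#' `rho = 1 - 6 * sum(d_i^2) / (n * (n^2 - 1))`, where `d_i` is the per-node
#' rank difference. When either input carries ties (fractional ranks), the
#' closed form is no longer exact and the product-moment correlation of the
#' rank vectors is used instead; the two paths agree exactly in the tie-free
#' case. Inputs that are not already ranks are ranked first, so arbitrary
#' monotone score vectors (e.g. mean-of-ranks group scores) can be compared.
#'
#' @param r1,r2 Numeric vectors of equal length `n >= 2`: ranking vectors, or
#'   score vectors to be ranked ascending before comparison.
#' @return Correlation in `[-1, 1]`. A fully tied (constant) vector carries
#'   no ordering information and yields 0.
#' @examples
#' spearman_rank(c(1, 4, 3, 2, 5), c(1, 2, 3, 4, 5)) # 0.6
#' @export
spearman_rank <- function(r1, r2) {
  if (!is.numeric(r1) || !is.numeric(r2)) {
    abort_bad_arg("r1/r2", "be numeric vectors")
  }
  n <- length(r1)
  if (length(r2) != n) abort_bad_arg("r2", "have the same length as `r1`")
  if (n < 2) abort_bad_arg("r1", "have length >= 2")
  if (anyNA(r1) || anyNA(r2)) abort_bad_arg("r1/r2", "not contain missing values")
  # ranking a valid ranking vector is the identity, so this is safe for both
  # ranks and raw scores
  r1 <- rank(r1, ties.method = "average")
  r2 <- rank(r2, ties.method = "average")
  tie_free <- function(r) length(unique(r)) == length(r)
  if (tie_free(r1) && tie_free(r2)) {
    1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
  } else {
    # a fully tied vector carries no ordering information: no monotone
    # association, correlation 0
    if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
      return(0)
    }
    stats::cor(r1, r2)
  }
}

#' Composite hubness score and ranking
#'
#' The hubness of a node is the arithmetic mean of its ranks across the five
#' node measures (degree, strength, coreness, betweenness, closeness); a lower
#' score is more hub-like. The hubness ranking ranks these scores ascending,
#' so the node with the best average rank gets hubness rank 1. Equal measure
#' weights are the default; `weights` allows sensitivity analyses.
#'
#' @param measures A measure table as returned by [measure_all()]: a data frame
#'   with a `node` column and columns `degree`, `strength`, `coreness`,
#'   `betweenness`, `closeness`.
#' @param weights Optional numeric vector of five non-negative measure weights
#'   (normalised internally); defaults to equal weights.
#' @return A tibble with columns `node`, `hubness_score`, `hubness_rank`.
#' @export
hubness <- function(measures, weights = NULL) {
  cols <- c("degree", "strength", "coreness", "betweenness", "closeness")
  missing_cols <- setdiff(cols, names(measures))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf("`measures` is missing column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "hubrank_error_validation"
    )
  }
  if (is.null(weights)) weights <- rep(1, 5)
  if (length(weights) != 5 || any(weights < 0) || sum(weights) == 0) {
    abort_bad_arg("weights", "be five non-negative numbers with a positive sum")
  }
  weights <- weights / sum(weights)
  rank_mat <- vapply(cols, function(m) rank_vector(measures[[m]]), numeric(nrow(measures)))
  score <- as.numeric(rank_mat %*% weights)
  tibble::tibble(
    node = if ("node" %in% names(measures)) measures$node else paste0("roi_", seq_along(score)),
    hubness_score = score,
    hubness_rank = rank_vector(score, descending = FALSE)
  )
}
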