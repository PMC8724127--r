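# Group-level aggregation of subject connectomes: aggregate-then-measure
# (ATM) versus measure-then-aggregate (MTA), and their representation power.

MEASURE_NAMES <- c("degree", "strength", "coreness", "betweenness", "closeness")
ALL_MEASURES <- c(MEASURE_NAMES, "hubness")

check_measure <- function(measure) {
  if (!is.character(measure) || length(measure) != 1 || !measure %in% ALL_MEASURES) {
    abort_bad_arg("measure", sprintf("be one of %s", paste(ALL_MEASURES, collapse = ", ")))
  }
  measure
}

#' Per-subject ranking vectors for all measures
#'
#' Computes, for every subject, the ranking vector of each of the five node
#' measures plus the composite hubness ranking. This is the expensive step of
#' measure-then-aggregate analyses; computing it once and passing the result
#' to [aggregate_mta()], [representation_power()] and friends avoids repeated
#' per-subject graph computations.
#'
#' @param pop A `subject_population` or a list of connectivity matrices.
#' @return A `subject_ranks` array of dimension nodes x 6 measures x
#'   subjects, rank 1 = top.
#' @export
subject_ranks <- function(pop) {
  subjects <- as_subject_list(pop)
  ids <- node_ids(subjects[[1]])
  arr <- array(
    NA_real_,
    dim = c(length(ids), length(ALL_MEASURES), length(subjects)),
    dimnames = list(ids, ALL_MEASURES, NULL)
  )
  for (s in seq_along(subjects)) {
    mt <- measure_all(subjects[[s]])
    for (m in MEASURE_NAMES) arr[, m, s] <- rank_vector(mt[[m]])
    arr[, "hubness", s] <- hubness(mt)$hubness_rank
  }
  structure(arr, class = c("subject_ranks", "array"))
}

new_group_ranking <- function(node, score, method, measure) {
  structure(
    tibble::tibble(node = node, score = score),
    method = method, measure = measure,
    class = c("group_ranking", class(tibble::tibble()))
  )
}

#' Aggregate-then-measure (ATM) group ranking
#'
#' Averages the subjects' weighted connectivity matrices elementwise into one
#' aggregate connectome, computes the requested measure on it, and ranks the
#' nodes. An edge is present in the aggregate binary graph whenever its mean
#' weight is positive, so the aggregate topology is the union of the
#' subjects' edge sets; `prevalence` optionally keeps only edges present in
#' at least that fraction of subjects (0 disables the threshold, the
#' default).
#'
#' @param pop A `subject_population` or list of connectivity matrices.
#' @param measure One of `"degree"`, `"strength"`, `"coreness"`,
#'   `"betweenness"`, `"closeness"`, `"hubness"`.
#' @param prevalence Minimum fraction of subjects an edge must appear in to
#'   survive in the aggregate (default 0 = keep all).
#' @return A `group_ranking` tibble with columns `node` and `score` (here the
#'   aggregate ranking, rank 1 = top).
#' @export
aggregate_atm <- function(pop, measure, prevalence = 0) {
  subjects <- as_subject_list(pop)
  measure <- check_measure(measure)
  prevalence <- check_fraction(prevalence, "prevalence")
  mean_W <- Reduce(`+`, subjects) / length(subjects)
  if (prevalence > 0) {
    presence <- Reduce(`+`, lapply(subjects, function(W) (W > 0) * 1)) / length(subjects)
    mean_W[presence < prevalence] <- 0
  }
  mt <- measure_all(mean_W)
  score <- if (measure == "hubness") {
    hubness(mt)$hubness_rank
  } else {
    unname(rank_vector(mt[[measure]]))
  }
  new_group_ranking(mt$node, as.numeric(score), "ATM", measure)
}

#' Measure-then-aggregate (MTA) group ranking
#'
#' Ranks the nodes within each subject's connectome first (with respect to
#' the requested measure, or the composite hubness ranking), then averages
#' the per-node ranks across subjects. The mean rank is kept as the group
#' score rather than re-ranked: Spearman comparisons are invariant to the
#' monotone re-ranking except under ties, and the raw mean is the more
#' informative quantity.
#'
#' @inheritParams aggregate_atm
#' @param ranks Optional precomputed [subject_ranks()] array.
#' @return A `group_ranking` tibble with columns `node` and `score` (mean of
#'   per-subject ranks; lower = more hub-like).
#' @export
aggregate_mta <- function(pop, measure, ranks = NULL) {
  measure <- check_measure(measure)
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  score <- rowMeans(ranks[, measure, , drop = FALSE], dims = 1)
  new_group_ranking(dimnames(ranks)[[1]], as.numeric(score), "MTA", measure)
}

#' Representation power of a group ranking
#'
#' The Spearman correlation between a group-level ranking and each individual
#' subject's own ranking for the same measure; the mean over subjects
#' summarises how well the group ranking represents the population.
#'
#' @param group A `group_ranking` from [aggregate_atm()] or
#'   [aggregate_mta()].
#' @inheritParams aggregate_mta
#' @return A `representation_power` tibble with columns `subject` and
#'   `correlation`; the mean is available via [glance()] or
#'   `attr(x, "mean_correlation")`.
#' @export
representation_power <- function(group, pop, ranks = NULL) {
  if (!inherits(group, "group_ranking")) {
    abort_bad_arg("group", "be a group_ranking")
  }
  measure <- attr(group, "measure")
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  if (!identical(group$node, dimnames(ranks)[[1]])) {
    abort_bad_arg("pop", "share the group ranking's node index")
  }
  n_subj <- dim(ranks)[3]
  cors <- vapply(seq_len(n_subj), function(s) {
    spearman_rank(group$score, ranks[, measure, s])
  }, numeric(1))
  structure(
    tibble::tibble(subject = seq_len(n_subj), correlation = cors),
    method = attr(group, "method"), measure = measure,
    mean_correlation = mean(cors),
    class = c("representation_power", class(tibble::tibble()))
  )
}

#' Compare ATM and MTA representation power across measures
#'
#' Computes both group rankings for each requested measure and their
#' per-subject representation correlations, sharing one pass of per-subject
#' measures.
#'
#' @inheritParams aggregate_mta
#' @param measures Character vector of measures (default: all five plus
#'   hubness).
#' @return An `aggregation_comparison` tibble with columns `measure`,
#'   `method`, `subject`, `correlation`; per measure-method means via
#'   [glance()].
#' @export
compare_aggregation <- function(pop, measures = ALL_MEASURES, ranks = NULL) {
  measures <- vapply(measures, check_measure, character(1))
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  rows <- purrr::map(measures, function(m) {
    dplyr::bind_rows(
      dplyr::mutate(
        tibble::as_tibble(representation_power(aggregate_atm(pop, m), pop, ranks)),
        measure = m, method = "ATM"
      ),
      dplyr::mutate(
        tibble::as_tibble(representation_power(aggregate_mta(pop, m, ranks), pop, ranks)),
        measure = m, method = "MTA"
      )
    )
  })
  structure(
    dplyr::bind_rows(rows)[, c("measure", "method", "subject", "correlation")],
    class = c("aggregation_comparison", class(tibble::tibble()))
  )
}

#' Pairwise correlation of group-level measure rankings
#'
#' Computes the MTA group ranking for the five node measures and the
#' composite hubness, then all pairwise Spearman correlations between the six
#' group rank score vectors.
#'
#' @inheritParams aggregate_mta
#' @return A symmetric 6 x 6 correlation matrix with unit diagonal.
#' @export
measure_intercorrelation <- function(pop, ranks = NULL) {
  if (is.null(ranks)) ranks <- subject_ranks(pop)
  scores <- vapply(
    ALL_MEASURES,
    function(m) aggregate_mta(pop, m, ranks)$score,
    numeric(dim(ranks)[1])
  )
  out <- matrix(1, 6, 6, dimnames = list(ALL_MEASURES, ALL_MEASURES))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      out[i, j] <- out[j, i] <- spearman_rank(scores[, i], scores[, j])
    }
  }
  out
}
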