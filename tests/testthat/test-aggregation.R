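# Group-level aggregation: ATM, MTA, representation power and the measure
# intercorrelation table.

zero_noise_pop <- function(seed = 41, n_subjects = 5) {
  generate_population(population_spec(
    n_subjects = n_subjects, n_parcels_per_hemisphere = 4, rois_per_parcel = 3,
    weight_noise_sigma = 0, edge_flip_prob = 0, seed = seed
  ))
}

test_that("identical subjects: ATM and MTA reproduce the common ranking", {
  pop <- zero_noise_pop()
  ind <- rank_vector(measure_all(pop$subjects[[1]])$degree)
  atm <- aggregate_atm(pop, "degree")
  mta <- aggregate_mta(pop, "degree")
  expect_equal(atm$score, unname(ind))
  expect_equal(mta$score, unname(ind))
})

test_that("single-subject populations give representation power 1", {
  pop <- generate_population(population_spec(
    n_subjects = 1, n_parcels_per_hemisphere = 3, rois_per_parcel = 3, seed = 2
  ))
  mta <- aggregate_mta(pop, "hubness")
  rp <- representation_power(mta, pop)
  expect_equal(rp$correlation, 1)
})

test_that("zero-noise populations: both methods have representation power 1", {
  pop <- zero_noise_pop()
  rk <- subject_ranks(pop)
  for (m in c("degree", "strength", "hubness")) {
    expect_equal(attr(representation_power(aggregate_atm(pop, m), pop, rk), "mean_correlation"), 1)
    expect_equal(attr(representation_power(aggregate_mta(pop, m, rk), pop, rk), "mean_correlation"), 1)
  }
})

test_that("exactly reversed subject rankings average to (n+1)/2 under MTA", {
  n <- 9
  r <- as.numeric(1:n)
  ranks <- array(
    c(rep(r, 6), rep(rev(r), 6)),
    dim = c(n, 6, 2),
    dimnames = list(paste0("v", 1:n), c(
      "degree", "strength", "coreness",
      "betweenness", "closeness", "hubness"
    ), NULL)
  )
  mta <- aggregate_mta(NULL, "degree", ranks = ranks)
  expect_equal(mta$score, rep((n + 1) / 2, n))
})

test_that("disjoint edge sets: ATM degree ranking equals the union graph's", {
  W1 <- graph_from_edges(6, rbind(c(1, 2), c(2, 3), c(1, 4)), w = 0.8)
  W2 <- graph_from_edges(6, rbind(c(4, 5), c(5, 6), c(3, 6), c(2, 6)), w = 1.4)
  rownames(W1) <- colnames(W1) <- rownames(W2) <- colnames(W2) <- paste0("v", 1:6)
  atm <- aggregate_atm(list(W1, W2), "degree")
  union_deg <- rowSums((W1 + W2) > 0)
  expect_equal(atm$score, unname(rank_vector(union_deg)))
})

test_that("MTA is invariant to subject order", {
  pop <- generate_population(population_spec(
    n_subjects = 6, n_parcels_per_hemisphere = 3, rois_per_parcel = 3, seed = 7
  ))
  shuffled <- pop$subjects[c(4, 2, 6, 1, 5, 3)]
  expect_equal(
    aggregate_mta(pop, "hubness")$score,
    aggregate_mta(shuffled, "hubness")$score
  )
})

test_that("MTA matches a from-scratch rank-then-mean recomputation", {
  pop <- generate_population(population_spec(
    n_subjects = 5, n_parcels_per_hemisphere = 3, rois_per_parcel = 3, seed = 19
  ))
  mta <- aggregate_mta(pop, "betweenness")
  manual <- rowMeans(vapply(
    pop$subjects,
    function(W) unname(rank_vector(measure_all(W)$betweenness)),
    numeric(18)
  ))
  expect_equal(mta$score, manual)
})

test_that("representation power validates the node index", {
  pop <- zero_noise_pop(n_subjects = 2)
  g <- aggregate_mta(pop, "degree")
  other <- generate_population(population_spec(
    n_subjects = 2, n_parcels_per_hemisphere = 2, rois_per_parcel = 2, seed = 1
  ))
  expect_error(representation_power(g, other), class = "hubrank_error_validation")
})

test_that("MTA beats ATM on noisy populations for topology-sensitive measures", {
  means <- list()
  for (s in 1:5) {
    pop <- generate_population(population_spec(
      n_subjects = 15, n_parcels_per_hemisphere = 8, rois_per_parcel = 3,
      seed = 200 + s
    ))
    means[[s]] <- glance(compare_aggregation(pop, measures = c("degree", "coreness")))
  }
  avg <- dplyr::summarise(
    dplyr::bind_rows(means),
    m = mean(.data$mean_correlation), .by = c("measure", "method")
  )
  for (meas in c("degree", "coreness")) {
    expect_gte(
      avg$m[avg$measure == meas & avg$method == "MTA"],
      avg$m[avg$measure == meas & avg$method == "ATM"]
    )
  }
})

test_that("measure intercorrelation table is symmetric with unit diagonal", {
  pop <- generate_population(population_spec(
    n_subjects = 10, n_parcels_per_hemisphere = 6, rois_per_parcel = 3,
    hub_fraction = 0.15, hub_weight_boost = 4, seed = 47
  ))
  M <- measure_intercorrelation(pop)
  expect_equal(dim(M), c(6, 6))
  expect_equal(unname(diag(M)), rep(1, 6))
  expect_equal(M, t(M))
  expect_true(all(M >= -1 & M <= 1))
  # on hub-structured data, degree is hubness' strongest correlate
  hub_row <- M["hubness", setdiff(colnames(M), "hubness")]
  expect_equal(names(which.max(hub_row)), "degree")
})

test_that("empty populations are rejected", {
  expect_error(aggregate_atm(list(), "degree"), class = "hubrank_error_validation")
})
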