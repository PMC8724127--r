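# The synthetic population generator: degeneracies, determinism, injected
# effects, label volumes and streamline round trips.

small_spec <- function(...) {
  population_spec(
    n_subjects = 4, n_parcels_per_hemisphere = 4, rois_per_parcel = 3, ...
  )
}

test_that("zero-noise populations degenerate to the base matrix", {
  pop <- generate_population(small_spec(
    weight_noise_sigma = 0, edge_flip_prob = 0, seed = 13
  ))
  for (W in pop$subjects) expect_equal(W, pop$base_matrix)
})

test_that("populations are bitwise reproducible under the same seed", {
  p1 <- generate_population(small_spec(seed = 99))
  p2 <- generate_population(small_spec(seed = 99))
  expect_identical(p1$base_matrix, p2$base_matrix)
  expect_identical(p1$subjects, p2$subjects)
  p3 <- generate_population(small_spec(seed = 100))
  expect_false(identical(p1$subjects, p3$subjects))
})

test_that("every subject matrix is symmetric, hollow and non-negative", {
  pop <- generate_population(small_spec(seed = 5, edge_flip_prob = 0.2))
  n <- 2 * 4 * 3
  expect_equal(nrow(pop$node_info), n)
  for (W in pop$subjects) {
    expect_equal(dim(W), c(n, n))
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0))
  }
})

test_that("invalid spec fields are rejected by name", {
  expect_error(population_spec(base_density = 0), "base_density")
  expect_error(population_spec(edge_flip_prob = 1), "edge_flip_prob")
  expect_error(population_spec(hub_weight_boost = 0.5), "hub_weight_boost")
  expect_error(population_spec(n_subjects = 0), "n_subjects")
  expect_error(
    population_spec(asymmetry_effects = c("99" = 2)),
    "asymmetry_effects"
  )
})

test_that("injected asymmetry doubles left-vs-right mean strength", {
  # the right homolog also touches a few scaled cross-hemisphere edges, so
  # the ratio converges to delta from below as the network grows; test at a
  # size where that contamination is small
  delta <- 2
  pop <- generate_population(population_spec(
    n_subjects = 80, n_parcels_per_hemisphere = 10, rois_per_parcel = 3,
    asymmetry_effects = c("2" = delta), seed = 17
  ))
  info <- pop$node_info
  left <- which(info$parcel == 2 & info$hemisphere == "L")
  right <- which(info$parcel == 2 + 10 & info$hemisphere == "R")
  strengths <- vapply(pop$subjects, rowSums, numeric(nrow(info)))
  ratio <- mean(strengths[left, ]) / mean(strengths[right, ])
  # construction oracle: the ratio the base matrix itself encodes (delta, up
  # to the doubly-scaled within-parcel edges)
  base_s <- rowSums(pop$base_matrix)
  base_ratio <- mean(base_s[left]) / mean(base_s[right])
  expect_gt(base_ratio, delta * 0.85)
  expect_lt(base_ratio, delta * 1.15)
  expect_equal(ratio, base_ratio, tolerance = 0.1)
})

test_that("left-right strength separation grows monotonically with delta", {
  sep <- vapply(c(1, 1.5, 2), function(d) {
    pop <- generate_population(population_spec(
      n_subjects = 40, n_parcels_per_hemisphere = 4, rois_per_parcel = 3,
      asymmetry_effects = c("1" = d), seed = 23
    ))
    info <- pop$node_info
    left <- which(info$parcel == 1 & info$hemisphere == "L")
    right <- which(info$parcel == 5 & info$hemisphere == "R")
    strengths <- vapply(pop$subjects, rowSums, numeric(nrow(info)))
    mean(strengths[left, ]) - mean(strengths[right, ])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
  expect_lt(abs(sep[1]), max(abs(sep)) * 0.5) # delta = 1 injects nothing systematic
})

test_that("a heterogeneity gradient orders expected strength within parcels", {
  pop <- generate_population(population_spec(
    n_subjects = 30, n_parcels_per_hemisphere = 4, rois_per_parcel = 4,
    heterogeneity_slope = 2, hub_fraction = 0, seed = 29
  ))
  info <- pop$node_info
  strengths <- rowMeans(vapply(pop$subjects, rowSums, numeric(nrow(info))))
  first <- mean(strengths[info$position == 1])
  last <- mean(strengths[info$position == 4])
  expect_gt(last, first * 1.5)
})

test_that("label volumes hit requested voxel counts exactly", {
  v1 <- generate_label_volume(1, 400, seed = 3)
  expect_equal(sum(v1$grid == 1), 400)
  expect_equal(sum(v1$grid > 0), 400)
  v2 <- generate_label_volume(2, c(3000, 236), seed = 4)
  expect_equal(sum(v2$grid == 1), 3000)
  expect_equal(sum(v2$grid == 2), 236)
  expect_identical(v2$grid, generate_label_volume(2, c(3000, 236), seed = 4)$grid)
})

test_that("label volume capacity violations raise a capacity error", {
  expect_error(
    generate_label_volume(1, 1000, seed = 1, dims = c(5, 5, 5)),
    class = "hubrank_error_capacity"
  )
})

test_that("streamline tables are empty for the zero matrix", {
  Z <- matrix(0, 3, 3)
  sl <- generate_streamlines(Z, c(roi_1 = 10, roi_2 = 10, roi_3 = 10), seed = 1)
  expect_equal(nrow(sl), 0)
})

test_that("a single edge round-trips exactly through the weight formula", {
  W <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  W["a", "b"] <- W["b", "a"] <- 0.05
  sizes <- c(a = 40, b = 40)
  sl <- generate_streamlines(W, sizes, length_range = c(50, 50), seed = 2)
  expect_true(all(abs(mean(sl$length_mm) - 50) < 1e-9))
  W2 <- build_weighted_matrix(sl, sizes)
  # only integer rounding of the count separates the two
  n_exact <- 0.05 * 50 * (40 + 40) / 2
  expect_equal(W2["a", "b"], round(n_exact) * (1 / 50) * (2 / 80))
})

test_that("random matrices round-trip with near-perfect strength rankings", {
  W <- random_graph(20, 0.3, seed = 31, weighted = TRUE)
  rownames(W) <- colnames(W) <- paste0("r", 1:20)
  sizes <- stats::setNames(rep(25, 20), rownames(W))
  sl <- generate_streamlines(W, sizes, length_range = c(30, 60), seed = 32)
  W2 <- build_weighted_matrix(sl, sizes)
  expect_gte(spearman_rank(rowSums(W2), rowSums(W)), 0.99)
  rel_err <- abs(W2[W > 0] - W[W > 0]) / W[W > 0]
  expect_lt(stats::median(rel_err), 0.05)
})
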