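# Downstream analyses: sample-size curves, consistent hubs, hemispheric
# asymmetry and intraparcel heterogeneity.

measure_dims <- c(
  "degree", "strength", "coreness", "betweenness", "closeness", "hubness"
)

ranks_array <- function(mat_list) {
  # build a subject_ranks-shaped array from per-subject hubness rank vectors,
  # replicating each across all six measure slots
  n <- length(mat_list[[1]])
  arr <- array(NA_real_, dim = c(n, 6, length(mat_list)), dimnames = list(
    paste0("v", seq_len(n)), measure_dims, NULL
  ))
  for (s in seq_along(mat_list)) arr[, , s] <- matrix(mat_list[[s]], n, 6)
  arr
}

test_that("zero-noise populations give correlation 1 at every sample size", {
  pop <- generate_population(population_spec(
    n_subjects = 10, n_parcels_per_hemisphere = 4, rois_per_parcel = 3,
    weight_noise_sigma = 0, edge_flip_prob = 0, seed = 3
  ))
  ssc <- sample_size_curve(pop, sizes = c(1, 2, 5, 10), n_replicates = 10, seed = 4)
  expect_true(all(ssc$correlation == 1))
})

test_that("the full-population sample reproduces the reference exactly", {
  pop <- generate_population(population_spec(
    n_subjects = 8, n_parcels_per_hemisphere = 4, rois_per_parcel = 3, seed = 5
  ))
  rk <- subject_ranks(pop)
  ssc <- sample_size_curve(pop, sizes = 8, n_replicates = 5, seed = 6, ranks = rk)
  expect_true(all(ssc$correlation == 1))
  # determinism and replicate count
  ssc2 <- sample_size_curve(pop, sizes = c(2, 4), n_replicates = 7, seed = 9, ranks = rk)
  ssc3 <- sample_size_curve(pop, sizes = c(2, 4), n_replicates = 7, seed = 9, ranks = rk)
  expect_identical(tibble::as_tibble(ssc2), tibble::as_tibble(ssc3))
  expect_equal(nrow(ssc2), 14)
  expect_error(
    sample_size_curve(pop, sizes = 9, n_replicates = 2, ranks = rk),
    class = "hubrank_error_validation"
  )
})

test_that("mean sample-size correlations are non-decreasing on noisy data", {
  pop <- generate_population(population_spec(
    n_subjects = 30, n_parcels_per_hemisphere = 6, rois_per_parcel = 3, seed = 8
  ))
  ssc <- sample_size_curve(pop, sizes = c(1, 3, 10, 30), n_replicates = 50, seed = 10)
  g <- glance(ssc)
  expect_false(is.unsorted(g$mean_correlation))
  expect_equal(g$mean_correlation[g$size == 30], 1)
})

test_that("five identical rankings yield exactly the top-quantile nodes", {
  r <- as.numeric(1:10)
  arr <- ranks_array(list(r))
  hs <- top_consistent_hubs(NULL, quantile = 0.2, ranks = arr)
  expect_setequal(hs$hubs, c("v1", "v2"))
})

test_that("disjoint per-measure top sets yield an empty hub set", {
  n <- 10
  arr <- array(NA_real_, dim = c(n, 6, 1), dimnames = list(
    paste0("v", 1:n), measure_dims, NULL
  ))
  # give measure m the top-2 set {v(2m-1), v(2m)} so the five sets are disjoint
  for (m in 1:5) {
    v <- 10 + as.numeric(1:n)
    v[c(2 * m - 1, 2 * m)] <- c(1, 2)
    arr[, m, 1] <- v
  }
  arr[, 6, 1] <- 10 + as.numeric(1:n)
  hs <- top_consistent_hubs(NULL, quantile = 0.2, ranks = arr)
  expect_length(hs$hubs, 0)
})

test_that("hub sets match a brute-force intersection oracle and are monotone", {
  pop <- generate_population(population_spec(
    n_subjects = 6, n_parcels_per_hemisphere = 5, rois_per_parcel = 3, seed = 21
  ))
  rk <- subject_ranks(pop)
  hs <- top_consistent_hubs(pop, quantile = 0.2, ranks = rk)
  n <- dim(rk)[1]
  m_top <- floor(0.2 * n)
  oracle <- Reduce(intersect, lapply(
    c("degree", "strength", "coreness", "betweenness", "closeness"),
    function(m) {
      sc <- rowMeans(rk[, m, ])
      names(sort(sc))[seq_len(m_top)]
    }
  ))
  expect_setequal(hs$hubs, oracle)
  sets <- lapply(c(0.1, 0.2, 0.4, 0.8), function(q) {
    top_consistent_hubs(pop, quantile = q, ranks = rk)$hubs
  })
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("parcel medians follow the odd and even count conventions", {
  map <- tibble::tibble(
    node = paste0("v", 1:7),
    parcel = c(1, 1, 1, 2, 2, 2, 2) + 0L,
    hemisphere = "L"
  )
  arr <- ranks_array(list(c(10, 20, 30, 10, 20, 30, 40)))
  dimnames(arr)[[1]] <- map$node
  tab <- parcel_rank_table(NULL, map = map, ranks = arr)
  expect_equal(tab$median_rank[tab$parcel == 1], 20)
  expect_equal(tab$median_rank[tab$parcel == 2], 25)
  # single-ROI parcels keep the ROI's rank
  map1 <- tibble::tibble(node = paste0("v", 1:3), parcel = 1:3, hemisphere = "L")
  arr1 <- ranks_array(list(c(3, 1, 2)))
  dimnames(arr1)[[1]] <- map1$node
  tab1 <- parcel_rank_table(NULL, map = map1, ranks = arr1)
  expect_equal(tab1$median_rank, c(3, 1, 2))
})

test_that("identical left and right rank tables are classified symmetric everywhere", {
  # zero-noise mirror-symmetric population: the left and right tables coincide
  pop <- generate_population(population_spec(
    n_subjects = 10, n_parcels_per_hemisphere = 5, rois_per_parcel = 3,
    weight_noise_sigma = 0, edge_flip_prob = 0, seed = 33
  ))
  tab <- parcel_rank_table(pop)
  rep <- hemispheric_asymmetry(tab)
  expect_true(all(rep$classification == "symmetric"))
  counts <- attr(rep, "class_counts")
  expect_equal(
    counts[["left-dominant"]] + counts[["right-dominant"]] + counts[["symmetric"]],
    nrow(rep)
  )
})

test_that("an injected left shift is detected and labels are equivariant", {
  pop <- generate_population(population_spec(
    n_subjects = 25, n_parcels_per_hemisphere = 8, rois_per_parcel = 3, seed = 37
  ))
  tab <- parcel_rank_table(pop)
  n <- attr(tab, "n_nodes")
  shifted <- tab
  sel <- shifted$parcel == 2 & shifted$hemisphere == "L"
  shifted$median_rank[sel] <- pmax(1, shifted$median_rank[sel] - 0.2 * n)
  rep <- hemispheric_asymmetry(shifted, pairs = attr(tab, "homolog_pairs"), n_units = n)
  expect_equal(rep$classification[rep$parcel_left == 2], "left-dominant")
  # swap hemispheres: the same parcel must flip to right-dominant
  swapped <- shifted
  swapped$hemisphere <- ifelse(swapped$hemisphere == "L", "R", "L")
  swapped$parcel <- ifelse(swapped$parcel <= 8, swapped$parcel + 8, swapped$parcel - 8)
  rep2 <- hemispheric_asymmetry(swapped, pairs = attr(tab, "homolog_pairs"), n_units = n)
  expect_equal(rep2$classification[rep2$parcel_left == 2], "right-dominant")
  cc1 <- attr(rep, "class_counts")
  cc2 <- attr(rep2, "class_counts")
  expect_equal(cc1[["left-dominant"]], cc2[["right-dominant"]])
  expect_equal(cc1[["right-dominant"]], cc2[["left-dominant"]])
})

test_that("the asymmetry test controls its type-I error on the symmetric null", {
  flagged <- 0
  pairs_total <- 0
  for (s in 1:4) {
    pop <- generate_population(population_spec(
      n_subjects = 20, n_parcels_per_hemisphere = 10, rois_per_parcel = 2,
      seed = 400 + s
    ))
    rep <- hemispheric_asymmetry(parcel_rank_table(pop))
    flagged <- flagged + sum(rep$classification != "symmetric")
    pairs_total <- pairs_total + nrow(rep)
  }
  alpha <- 0.01
  mc_se <- sqrt(alpha * (1 - alpha) / pairs_total)
  expect_lte(flagged / pairs_total, alpha + 3 * mc_se)
})

test_that("too few subjects for the paired test is an error", {
  pop <- generate_population(population_spec(
    n_subjects = 4, n_parcels_per_hemisphere = 3, rois_per_parcel = 2, seed = 2
  ))
  expect_error(
    hemispheric_asymmetry(parcel_rank_table(pop)),
    class = "hubrank_error_validation"
  )
})

test_that("interhemispheric correlation hits its limit cases", {
  # mirror-symmetric zero-noise population: left and right parcel medians equal
  pop <- generate_population(population_spec(
    n_subjects = 5, n_parcels_per_hemisphere = 6, rois_per_parcel = 3,
    weight_noise_sigma = 0, edge_flip_prob = 0, seed = 51
  ))
  g <- aggregate_mta(pop, "hubness")
  pr <- group_parcel_ranks(g, pop$node_info)
  pairs <- attr(parcel_rank_table(pop), "homolog_pairs")
  left <- pr$median_rank[match(pairs$parcel_left, pr$parcel)]
  right <- pr$median_rank[match(pairs$parcel_right, pr$parcel)]
  expect_equal(left, right)
  expect_equal(interhemispheric_correlation(left, right), 1)
  # anti-ordered halves
  expect_equal(interhemispheric_correlation(1:8, 8:1), -1)
  # independent halves: near-zero correlation in expectation
  cors <- vapply(1:200, function(s) {
    withr::with_seed(s, interhemispheric_correlation(stats::runif(20), stats::runif(20)))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.06)
})

test_that("heterogeneity report covers every parcel with sane spreads", {
  pop <- generate_population(population_spec(
    n_subjects = 8, n_parcels_per_hemisphere = 5, rois_per_parcel = 3, seed = 61
  ))
  g <- aggregate_mta(pop, "hubness")
  het <- intraparcel_heterogeneity(g, pop$node_info)
  expect_equal(nrow(het), 10)
  expect_true(all(het$max_rank >= het$min_rank))
  expect_true(all(het$iqr >= 0))
  # single-ROI parcels have zero spread
  map1 <- tibble::tibble(node = g$node, parcel = seq_along(g$node), hemisphere = "L")
  het1 <- intraparcel_heterogeneity(g, map1)
  expect_true(all(het1$iqr == 0))
  expect_true(all(het1$max_rank == het1$min_rank))
})

test_that("an injected within-parcel gradient inflates that parcel's spread", {
  # gradient injected into one parcel: its ROIs should span the group
  # ranking more widely than the gradient-free parcels
  pop <- generate_population(population_spec(
    n_subjects = 20, n_parcels_per_hemisphere = 6, rois_per_parcel = 5,
    base_density = 0.15, heterogeneity_slope = 5, heterogeneity_parcels = 1,
    hub_fraction = 0, seed = 71
  ))
  g <- aggregate_mta(pop, "hubness")
  het <- intraparcel_heterogeneity(g, pop$node_info)
  grad_iqr <- het$iqr[het$parcel %in% c(1, 7)]
  flat_iqr <- het$iqr[!het$parcel %in% c(1, 7)]
  expect_gt(min(grad_iqr), mean(flat_iqr))
})
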