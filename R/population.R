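# Synthetic connectome populations: a shared hub-bearing, modular base
# network plus per-subject weight noise and topology flips. These emulate the
# statistical structure that group-level rank aggregation assumes
# (inter-subject variability around a common hub architecture), so every
# downstream stage is testable without diffusion MRI data.

#' Specify a synthetic connectome population
#'
#' Defines the study conditions for [generate_population()]: network size and
#' modular layout, the designated hub architecture, and the two sources of
#' inter-subject variability (multiplicative lognormal weight noise and
#' Bernoulli edge presence flips). Optional per-parcel left/right weight
#' scaling injects hemispheric asymmetry, and a within-parcel gradient of
#' expected node strength injects intraparcel heterogeneity.
#'
#' The node count is `2 * n_parcels_per_hemisphere * rois_per_parcel`; nodes
#' are grouped into parcels (one module each), and left parcel `p` is
#' homologous to right parcel `p + n_parcels_per_hemisphere`.
#'
#' @param n_subjects Number of subjects in the population.
#' @param n_parcels_per_hemisphere Number of parcels per hemisphere.
#' @param rois_per_parcel Number of ROIs (nodes) per parcel.
#' @param base_density Baseline edge probability between parcels, in (0, 1];
#'   within-parcel density is four times higher (capped at 1), giving the
#'   modular structure typical of cortical networks.
#' @param hub_fraction Fraction of nodes designated ground-truth hubs.
#' @param hub_weight_boost Multiplicative factor (>= 1) applied to edge
#'   weights incident to hub nodes.
#' @param weight_noise_sigma Standard deviation of the per-subject,
#'   per-edge lognormal multiplicative weight noise (log scale, >= 0).
#' @param edge_flip_prob Probability in [0, 1) that a node pair's edge
#'   presence is toggled in a given subject.
#' @param asymmetry_effects Optional named numeric vector mapping left-parcel
#'   ids to a multiplicative scale factor delta applied to the incident
#'   weights of that parcel's left-hemisphere nodes.
#' @param heterogeneity_slope Within-parcel linear gradient of expected node
#'   connectivity: the last ROI of an affected parcel has expected incident
#'   edge mass `(1 + heterogeneity_slope)` times the first ROI's. The
#'   gradient acts on edge presence probability, so it is visible to both
#'   topology measures and strength.
#' @param heterogeneity_parcels Optional integer vector of left-parcel ids
#'   the gradient applies to (mirrored to their right homologs); `NULL`
#'   (default) applies it to every parcel.
#' @param seed Integer RNG seed; the whole population is deterministic in it.
#' @return A validated `population_spec` object.
#' @export
population_spec <- function(n_subjects = 50,
                            n_parcels_per_hemisphere = 25,
                            rois_per_parcel = 4,
                            base_density = 0.1,
                            hub_fraction = 0.1,
                            hub_weight_boost = 3,
                            weight_noise_sigma = 0.5,
                            edge_flip_prob = 0.05,
                            asymmetry_effects = NULL,
                            heterogeneity_slope = 0,
                            heterogeneity_parcels = NULL,
                            seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_parcels_per_hemisphere = check_count(n_parcels_per_hemisphere, "n_parcels_per_hemisphere"),
    rois_per_parcel = check_count(rois_per_parcel, "rois_per_parcel"),
    base_density = check_fraction(base_density, "base_density", lo = 0, hi = 1, lo_open = TRUE),
    hub_fraction = check_fraction(hub_fraction, "hub_fraction", lo = 0, hi = 1),
    hub_weight_boost = check_fraction(hub_weight_boost, "hub_weight_boost", lo = 1, hi = Inf),
    weight_noise_sigma = check_fraction(weight_noise_sigma, "weight_noise_sigma", lo = 0, hi = Inf),
    edge_flip_prob = check_fraction(edge_flip_prob, "edge_flip_prob", lo = 0, hi = 1, hi_open = TRUE),
    asymmetry_effects = asymmetry_effects,
    heterogeneity_slope = check_fraction(heterogeneity_slope, "heterogeneity_slope", lo = 0, hi = Inf),
    heterogeneity_parcels = heterogeneity_parcels,
    seed = check_count(seed, "seed", min = 0)
  )
  if (!is.null(heterogeneity_parcels)) {
    hp <- suppressWarnings(as.integer(heterogeneity_parcels))
    if (anyNA(hp) || any(hp < 1) || any(hp > spec$n_parcels_per_hemisphere)) {
      abort_bad_arg("heterogeneity_parcels", "name parcels within 1..n_parcels_per_hemisphere")
    }
    spec$heterogeneity_parcels <- hp
  }
  if (!is.null(asymmetry_effects)) {
    if (is.null(names(asymmetry_effects)) || !is.numeric(asymmetry_effects) ||
      any(asymmetry_effects <= 0)) {
      abort_bad_arg("asymmetry_effects", "be a named positive numeric vector (names are left parcel ids)")
    }
    p_ids <- suppressWarnings(as.integer(names(asymmetry_effects)))
    if (anyNA(p_ids) || any(p_ids < 1) || any(p_ids > spec$n_parcels_per_hemisphere)) {
      abort_bad_arg("asymmetry_effects", "name parcels within 1..n_parcels_per_hemisphere")
    }
  }
  structure(spec, class = "population_spec")
}

#' @exportS3Method base::print
print.population_spec <- function(x, ...) {
  n <- 2 * x$n_parcels_per_hemisphere * x$rois_per_parcel
  cat(sprintf(
    "<population_spec> %d subjects, %d nodes (%d parcels x %d ROIs x 2 hemispheres)\n",
    x$n_subjects, n, x$n_parcels_per_hemisphere, x$rois_per_parcel
  ))
  cat(sprintf(
    "  density %.3g, hub fraction %.3g (boost %.3g), noise sigma %.3g, flip prob %.3g, seed %d\n",
    x$base_density, x$hub_fraction, x$hub_weight_boost,
    x$weight_noise_sigma, x$edge_flip_prob, x$seed
  ))
  invisible(x)
}

node_metadata <- function(P, R) {
  nh <- P * R
  parcel_half <- rep(seq_len(P), each = R)
  tibble::tibble(
    node = sprintf("roi_%04d", seq_len(2 * nh)),
    parcel = c(parcel_half, parcel_half + P),
    hemisphere = rep(c("L", "R"), each = nh),
    homolog_parcel = c(parcel_half + P, parcel_half),
    position = rep(rep(seq_len(R), P), 2)
  )
}

sym_from_upper <- function(n, fill_fun) {
  M <- matrix(0, n, n)
  ut <- upper.tri(M)
  M[ut] <- fill_fun(sum(ut))
  M + t(M)
}

#' Generate a synthetic connectome population
#'
#' Builds a ground-truth base connectome — a modular (one block per parcel)
#' random weighted graph, mirror-symmetric across hemispheres, with designated
#' hub nodes whose incident expected weights are boosted — then derives one
#' matrix per subject by applying elementwise lognormal weight noise and
#' independent edge presence flips (new edges drawn at the base weight scale).
#' Left-hemisphere nodes of parcels named in `asymmetry_effects` have their
#' incident weights scaled by the given factor, breaking the mirror symmetry;
#' `heterogeneity_slope` imposes a within-parcel gradient of expected
#' strength. Deterministic given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return A `connectome_population` object: a list with `base_matrix`,
#'   `subjects` (list of connectivity matrices), `node_info` (tibble with
#'   node, parcel, hemisphere, homolog pairing), and `ground_truth`
#'   (hub node ids, asymmetric parcels, the spec).
#' @examples
#' pop <- generate_population(population_spec(
#'   n_subjects = 3, n_parcels_per_hemisphere = 4,
#'   rois_per_parcel = 3, seed = 7
#' ))
#' length(pop$subjects)
#' @export
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec")) {
    spec <- do.call(population_spec, as.list(spec))
  }
  P <- spec$n_parcels_per_hemisphere
  R <- spec$rois_per_parcel
  nh <- P * R
  n <- 2 * nh
  info <- node_metadata(P, R)
  seeds <- derive_seeds(spec$seed, spec$n_subjects + 1)

  built <- with_seed(seeds[1], {
    p_in <- min(1, 4 * spec$base_density)
    p_out <- spec$base_density
    parcel_half <- rep(seq_len(P), each = R)

    # hub nodes, chosen in mirror pairs
    n_hub_pairs <- round(spec$hub_fraction * n / 2)
    hub_left <- if (n_hub_pairs > 0) sort(sample.int(nh, n_hub_pairs)) else integer(0)
    hubs <- c(hub_left, hub_left + nh)
    # weight-scale node factors: hub boost + left/right asymmetry. Each of
    # the two factors scales an incident edge exactly once (max over the two
    # endpoints), so a scaled node's strength is the factor times its
    # unscaled strength
    f_hub <- rep(1, n)
    f_hub[hubs] <- spec$hub_weight_boost
    f_delta <- rep(1, n)
    if (!is.null(spec$asymmetry_effects)) {
      p_ids <- as.integer(names(spec$asymmetry_effects))
      for (k in seq_along(p_ids)) {
        left_nodes <- which(info$parcel == p_ids[k] & info$hemisphere == "L")
        f_delta[left_nodes] <- pmax(f_delta[left_nodes], spec$asymmetry_effects[k])
      }
    }
    # within-parcel gradient acts on edge presence, so it shows up in both
    # topology (degree, coreness, ...) and expected strength; mirror-symmetric
    h <- rep(1, n)
    if (R > 1 && spec$heterogeneity_slope > 0) {
      # normalized so the parcel keeps its average connectivity while its
      # first and last ROI differ by a factor (1 + slope): the gradient
      # spreads the parcel across the ranking instead of shifting it
      h <- (1 + spec$heterogeneity_slope * (info$position - 1) / (R - 1)) /
        (1 + spec$heterogeneity_slope / 2)
      if (!is.null(spec$heterogeneity_parcels)) {
        affected <- info$parcel %in% c(
          spec$heterogeneity_parcels,
          spec$heterogeneity_parcels + P
        )
        h[!affected] <- 1
      }
    }
    h_half <- h[seq_len(nh)]

    # per-parcel connectivity level (mirrored): cortical parcels differ in
    # how richly connected they are, which is what makes within-parcel rank
    # spread informative rather than saturated
    parcel_level <- stats::rlnorm(P, 0, 0.35)
    c_half <- parcel_level[parcel_half] * h_half

    # left-left block (mirrored to right-right)
    prob_half <- ifelse(outer(parcel_half, parcel_half, "=="), p_in, p_out)
    prob_half <- pmin(prob_half * outer(c_half, c_half), 1)
    A_LL <- sym_from_upper(nh, function(m) {
      stats::rbinom(m, 1, prob_half[upper.tri(prob_half)])
    })
    W_LL <- A_LL * sym_from_upper(nh, function(m) stats::rlnorm(m, 0, 0.5))
    # left-right block; mirror symmetry of the whole graph requires B = t(B)
    prob_lr <- pmin(p_out * outer(c_half, c_half), 1)
    B_pres <- matrix(0, nh, nh)
    ut_d <- upper.tri(B_pres, diag = TRUE)
    B_pres[ut_d] <- stats::rbinom(sum(ut_d), 1, prob_lr[ut_d])
    B_w <- matrix(0, nh, nh)
    B_w[ut_d] <- stats::rlnorm(sum(ut_d), 0, 0.5)
    B <- B_pres * B_w
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
    W <- rbind(cbind(W_LL, B), cbind(t(B), W_LL))

    edge_scale <- outer(f_hub, f_hub, pmax) * outer(f_delta, f_delta, pmax)
    W <- W * edge_scale
    diag(W) <- 0
    dimnames(W) <- list(info$node, info$node)
    list(base = W, hubs = info$node[hubs], edge_scale = edge_scale)
  })

  base <- built$base
  hubs <- built$hubs

  ut <- upper.tri(base)
  base_ut <- base[ut]
  # flipped-in edges are drawn from the same per-edge weight law as the base,
  # including the per-edge scale factors, so injected effects survive flips
  gw_ut <- built$edge_scale[ut]

  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    with_seed(seeds[s + 1], {
      m <- sum(ut)
      w <- base_ut
      if (spec$weight_noise_sigma > 0) {
        w <- w * exp(stats::rnorm(m, 0, spec$weight_noise_sigma))
      }
      if (spec$edge_flip_prob > 0) {
        flip <- stats::runif(m) < spec$edge_flip_prob
        new_w <- stats::rlnorm(m, 0, 0.5) * gw_ut
        w <- ifelse(flip, ifelse(w > 0, 0, new_w), w)
      }
      Ws <- matrix(0, n, n, dimnames = dimnames(base))
      Ws[ut] <- w
      Ws + t(Ws)
    })
  })

  structure(
    list(
      base_matrix = base,
      subjects = subjects,
      node_info = info,
      ground_truth = list(
        hubs = hubs,
        asymmetric_parcels = names(spec$asymmetry_effects),
        spec = spec
      )
    ),
    class = c("connectome_population", "subject_population")
  )
}

#' @exportS3Method base::print
print.connectome_population <- function(x, ...) {
  cat(sprintf(
    "<connectome_population> %d subjects, %d nodes, %d ground-truth hubs\n",
    length(x$subjects), nrow(x$node_info), length(x$ground_truth$hubs)
  ))
  invisible(x)
}

#' Wrap a list of connectivity matrices as a subject population
#'
#' All matrices must share the same dimensions and node ids. Node metadata
#' (parcel membership, hemisphere, homolog pairing) can be supplied for
#' downstream parcel-level analyses.
#'
#' @param subjects List of symmetric, hollow, non-negative matrices with a
#'   shared node index.
#' @param node_info Optional tibble with at least a `node` column matching the
#'   matrix dimnames; columns `parcel`, `hemisphere`, `homolog_parcel` enable
#'   parcel-level analyses.
#' @return A `subject_population` object.
#' @export
subject_population <- function(subjects, node_info = NULL) {
  if (!is.list(subjects) || length(subjects) == 0) {
    abort_bad_arg("subjects", "be a non-empty list of matrices")
  }
  ids <- node_ids(subjects[[1]])
  for (s in seq_along(subjects)) {
    validate_matrix(subjects[[s]], sprintf("subjects[[%d]]", s))
    if (!identical(dim(subjects[[s]]), dim(subjects[[1]])) ||
      !identical(node_ids(subjects[[s]]), ids)) {
      abort_bad_arg("subjects", "share one node index across all matrices")
    }
  }
  if (is.null(node_info)) {
    node_info <- tibble::tibble(node = ids)
  } else if (!all(ids %in% node_info$node)) {
    abort_bad_arg("node_info", "cover every node in the matrices")
  }
  structure(
    list(subjects = subjects, node_info = node_info),
    class = "subject_population"
  )
}

as_subject_list <- function(pop) {
  if (inherits(pop, "subject_population")) {
    pop$subjects
  } else if (is.list(pop) && length(pop) > 0 && is.matrix(pop[[1]])) {
    pop
  } else {
    abort_bad_arg("pop", "be a subject_population or a list of matrices")
  }
}

pop_node_info <- function(pop) {
  if (inherits(pop, "subject_population") && !is.null(pop$node_info)) {
    pop$node_info
  } else {
    tibble::tibble(node = node_ids(as_subject_list(pop)[[1]]))
  }
}
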