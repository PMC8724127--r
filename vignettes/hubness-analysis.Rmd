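---
title: "Rank-based group-level hubness analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based group-level hubness analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubrank)
```

## The problem

Structural connectomics represents each subject's brain as a weighted,
undirected network: nodes are gray-matter regions of interest (ROIs), edges
summarise the white-matter streamlines reconstructed between them. Two
questions drive this package:

1. **Which nodes are hubs?** A hub is highly connected and topologically
   central. Following the classical approach, five node measures are used as
   proxies — degree, strength, coreness, betweenness and closeness — and
   combined into a composite *hubness* score.
2. **How should many subjects be summarised into one group-level answer?**
   Subjects differ; a group statement about hubs has to aggregate over that
   variability without being dominated by it.

## From streamlines to a network

Each ROI becomes a node. For an unordered ROI pair $(i, j)$ with at least
one streamline, the edge weight is

$$w_{ij} = n_{ij}\cdot\frac{1}{L_{ij}}\cdot\frac{2}{V_i+V_j},$$

where $n_{ij}$ is the streamline count, $L_{ij}$ the mean streamline length
(mm) and $V_i, V_j$ the ROI voxel counts. The $1/L_{ij}$ term compensates
the long-fiber bias of deterministic tractography; the size term compensates
residual ROI size differences. The binary graph connects every pair with
positive weight by a unit edge; no threshold is applied
([`build_weighted_matrix()`], [`binarize()`]).

ROIs are produced by **sub-parcellation**: atlas parcels differ in volume by
a factor of ~30, so each parcel's voxels are split into
$k = \lfloor \text{voxels} / 400 \rfloor$ spatially compact clusters by
k-means on voxel coordinates (parcels under 400 voxels are kept whole).
A fair node-by-node comparison requires nodes of similar size; this
homogenisation provides it ([`determine_k()`], [`subparcellate_atlas()`]).

**k-means details.** The clustering uses Lloyd iterations with k-means++
initialisation, a squared-Euclidean objective on voxel centre coordinates in
mm, 10 restarts (best objective kept), a 300-iteration cap, and an explicit
seed. Empty clusters are reseeded at the voxel farthest from its current
centre. Contiguity is not enforced algorithmically — k-means cells are
contiguous for convex parcels — but every ROI is audited by 6-connectivity
flood fill and non-contiguous ROIs are reported as a warning, not an error.

## Measures, ranks and hubness

Strength is computed on the weighted matrix; degree, coreness, betweenness
and closeness on the binary graph, because their definitions here are
explicitly unweighted. Betweenness is normalised by the $(n-1)(n-2)/2$
eligible pairs so it reads as the *fraction* of shortest paths through the
node; endpoints are excluded and disconnected pairs contribute zero.
Closeness on a disconnected graph uses Wasserman–Faust component scaling
(reciprocal of the reachable distance sum times $(r-1)/(n-1)$), with an
isolated node at 0 — the definitions implicitly assume connectedness and a
warning is emitted when the scaling triggers.

Within a network, nodes are ranked per measure: rank 1 is the top node, ties
receive average (fractional) ranks, so ranks always sum to $n(n+1)/2$. The
**hubness score** of a node is the arithmetic mean of its five measure
ranks (lower = more hub-like); the hubness ranking ranks those scores
ascending. Equal weights are the default; `hubness(weights = ...)` exposes
them for sensitivity analyses. Two rankings are compared by Spearman's
$\rho = 1 - 6\sum d_i^2 / (n(n^2-1))$; with ties the product-moment
correlation of rank vectors is used (the two coincide in the tie-free case).
A fully tied vector carries no ordering information; its correlation with
anything is defined as 0.

### Numerical choices

Strength and betweenness values are stabilised to 12 significant digits
before ranking. Floating-point summation order otherwise splits values that
are exactly equal by graph symmetry (e.g. mirror-homologous nodes in a
symmetric network) into spurious distinct ranks; 12 digits is far below any
scientifically meaningful difference and far above accumulation noise.

## Group aggregation: ATM vs MTA

- **Aggregate-then-measure (ATM)**: average the weighted matrices
  elementwise, then measure and rank the aggregate connectome. The aggregate
  binary topology is the *union* of the subjects' edge sets (any positive
  mean weight), so with per-subject topology noise the aggregate densifies:
  an optional prevalence threshold (`aggregate_atm(prevalence =)`) keeps
  only edges present in a minimum fraction of subjects.
- **Measure-then-aggregate (MTA)**: rank nodes within each subject first,
  then average the per-node ranks across subjects. The mean rank is kept as
  the group score rather than re-ranked — Spearman comparisons are invariant
  to that monotone transformation except under ties, and the raw mean is the
  more informative value.

**Representation power** is the Spearman correlation between a group
ranking and each subject's own ranking, averaged over subjects. On noisy
synthetic populations MTA consistently dominates ATM for degree, coreness,
betweenness and closeness, while the two methods tie for strength (weight
averaging preserves the strength ordering while the union topology destroys
degree ordering). `compare_aggregation()` + `autoplot()` reproduce this
comparison on any population.

## Downstream analyses

- `sample_size_curve()`: repeatedly draw $n_s$ subjects (without
  replacement within a replicate; 100 replicates per size by default),
  compute the sample MTA hubness ranking, and correlate it with the
  full-population ranking. The curve rises steeply and plateaus; at the full
  population size the correlation is exactly 1.
- `top_consistent_hubs()`: nodes in the best 20% of the MTA group score for
  *all five* measures. Top sets contain $\lfloor q\,n \rfloor$ nodes with
  ties at the cutoff broken by node order, which makes the hub set monotone
  in the quantile.
- `parcel_rank_table()` / `hemispheric_asymmetry()`: sub-parcellation does
  not produce homologous ROIs across hemispheres, so hemispheric comparisons
  use parcels: per subject, a parcel's value is the *median* of its ROIs'
  hubness ranks (even counts: midpoint of the central pair). For each
  homologous pair the per-subject left-minus-right differences are tested
  with a two-sided paired Wilcoxon signed-rank test (no distributional
  assumption on rank data; exact for small tie-free samples; a paired
  t-test is available via `test = "t"`). A pair is dominant only when
  $p < 0.01$ **and** the absolute mean difference exceeds 5% of the number
  of ranked units — the margin keeps statistically detectable but tiny
  shifts classified as symmetric. The margin fraction, alpha, the test and
  an optional Benjamini–Hochberg correction (`adjust = "BH"`; default is
  raw p-values) are configurable. The same machinery gives the
  interhemispheric correlation (Spearman between left and right group-level
  parcel median ranks).
- `intraparcel_heterogeneity()`: per-parcel spread (min, max, median, IQR)
  of the group-level ROI hubness ranks; single-ROI parcels have zero spread
  by construction. Optionally correlates pair median rank with asymmetry
  magnitude.

## The synthetic population generator

Real diffusion-MRI populations are far beyond desk scale, so every analysis
here is exercised on synthetic populations with the statistical structure
the methods assume: a shared hub architecture plus inter-subject
variability. `population_spec()` fixes the conditions; `generate_population()`
is fully deterministic given the seed (one master seed, per-subject
sub-seeds derived from it).

**Base connectome.** A modular random graph: one block per parcel, with
within-parcel edge probability four times the baseline density (capped at
1) — cortical networks are modular, and sub-parcelled ROIs of one parcel
are strongly interconnected. Each parcel also receives a mirrored
*connectivity level* (lognormal, sd 0.35 on the log scale) multiplying the
presence probability of its incident edges: cortical parcels genuinely
differ in how richly connected they are, and without this diversity all
parcels are statistically exchangeable, which saturates within-parcel rank
spread and makes heterogeneity analyses vacuous. The base is
mirror-symmetric across hemispheres by construction (the right hemisphere
block copies the left; the interhemispheric block is symmetric under the
homolog map), so the un-injected generator is an exact null for asymmetry
analyses.

**Hubs.** A fraction of nodes (default 10%) is designated hubs, sampled in
mirror pairs; edge weights incident to a hub are multiplied by the boost
factor (default 3), each edge scaled exactly once (max over its two
endpoints), so a hub's expected strength is exactly boost × its unscaled
strength.

**Inter-subject variability.** Two mechanisms, both per subject and per
edge: multiplicative lognormal weight noise (sd 0.5 on the log scale,
roughly a ±65% one-sigma band — substantial but structure-preserving), and
independent presence flips with probability 0.05 (an existing edge vanishes,
a missing edge appears with a weight drawn from the same lognormal law as
base edges, including the per-edge scale factors). With both set to zero
every subject equals the base matrix exactly, which pins down all
zero-noise degeneracy properties.

**Injected effects for parameter recovery.**

- *Asymmetry*: `asymmetry_effects = c("7" = 2)` scales the incident weights
  of parcel 7's left-hemisphere nodes by 2 (again once per edge). The
  left/right mean strength ratio recovers the factor up to the doubly
  scaled within-parcel edges and the scaled cross-edges touching the right
  homolog — both shrink as the network grows.
- *Heterogeneity*: `heterogeneity_slope` imposes a within-parcel linear
  gradient of expected connectivity, acting on edge *presence* probability
  so that topology measures see it too. The profile is normalised to keep
  the parcel's average level unchanged while first and last ROI differ by
  the factor $(1 + \text{slope})$ — an un-normalised gradient would shift
  the whole parcel up the ranking instead of spreading it.
  `heterogeneity_parcels` restricts the gradient to chosen parcels, which is
  what a heterogeneity *contrast* needs: gradient parcels are compared
  against gradient-free parcels of the same population.

**What the generator does not emulate.** Streamline-level biases
(gyral-crown seeding, distance-dependent false negatives), geometric
embedding (no spatial distance effect on connection probability),
subject-level global scaling differences, and realistic degree
distributions beyond the modular-plus-hubs structure. Passing tests on
these populations therefore demonstrate the *statistical machinery* —
ranking, aggregation, testing, recovery of injected effects — not fidelity
to any real dataset's effect sizes.

## Problem sizes used in the checks

The package's test suite and the acceptance script run populations of 50
subjects × 200 nodes (25 parcels per hemisphere × 4 ROIs) for aggregation
comparisons, 100 subjects for sample-size curves, and 50 subjects × 600
nodes (100 parcels per hemisphere × 3 ROIs) for asymmetry recovery, with
20 independent populations for the ATM/MTA comparison. These sizes were
chosen so that Monte-Carlo error is small relative to the effects being
demonstrated while a full run remains comfortable on a laptop.

## Worked example

```{r example, eval = FALSE}
library(hubrank)

pop <- generate_population(population_spec(n_subjects = 50, seed = 1))

# ATM vs MTA representation power, all measures
cmp <- compare_aggregation(pop)
glance(cmp)
autoplot(cmp)

# sample-size curve
ssc <- sample_size_curve(pop, sizes = c(1, 2, 5, 10, 20, 50), seed = 1)
autoplot(ssc)

# hemispheric asymmetry on the symmetric null
rep <- hemispheric_asymmetry(parcel_rank_table(pop))
glance(rep)
```

## Known limitations

- The composite hubness weights the five measures equally; the measures are
  strongly intercorrelated, so the composite is dominated by their shared
  axis (degree correlates with it most strongly). The weights are exposed
  but no principled weighting is attempted.
- The asymmetry margin is interpreted as a fraction of the total number of
  ranked units applied to the absolute mean paired difference; other
  readings (e.g. a quantile band) are defensible, and the choice matters
  near the decision boundary.
- ATM is implemented with the strict-positivity binarization of the
  aggregate; with many subjects the aggregate approaches the complete graph
  and ATM degree rankings degenerate. That is a property of the method the
  package is designed to expose, not an artifact — use the prevalence
  threshold to explore intermediate behaviour.
- k-means sub-parcellation equalises voxel counts only approximately; the
  residual size differences are exactly what the $2/(V_i+V_j)$ weight term
  corrects.
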