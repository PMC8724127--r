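# hubrank

Rank-based group-level hubness analysis of structural brain connectomes.

## What problem this solves

Structural connectomics models each subject's brain as a weighted undirected
network — nodes are gray-matter regions of interest (ROIs), edge weights
summarise the tractography streamlines between them:

    w_ij = n_ij * (1 / L_ij) * (2 / (V_i + V_j))

with streamline count `n_ij`, mean streamline length `L_ij` (mm), and ROI
voxel counts `V_i`, `V_j`. Hub regions are identified from five node
measures — degree, strength, coreness, betweenness, closeness — combined
into a composite **hubness** score: the mean of a node's five within-network
ranks (rank 1 = top; a lower score is more hub-like). Rankings are compared
with Spearman's `rho = 1 - 6 * sum(d_i^2) / (n (n^2 - 1))`.

The methodological core is the comparison of two group-aggregation
strategies for populations of subjects:

- **ATM (aggregate-then-measure)** — average the connectivity matrices, then
  measure and rank the aggregate connectome;
- **MTA (measure-then-aggregate)** — rank nodes within each subject first,
  then average the ranks per node.

Their **representation power** is the mean Spearman correlation between the
group ranking and each subject's own ranking. The package also provides the
downstream analyses this enables: sample-size curves, consistent-hub
identification (top 20% in all five measures), hemispheric asymmetry testing
of homologous parcels (5% rank margin + paired Wilcoxon at p < 0.01), and
intraparcel heterogeneity of hubness ranks — plus atlas sub-parcellation
(k-means on voxel coordinates, one cluster per 400 voxels) and a synthetic
connectome population generator so the entire pipeline runs without any
imaging data.

Intended users: network-neuroscience researchers working with
connectivity matrices or streamline endpoint tables, and methodologists
studying group-aggregation behaviour of graph statistics.

## Worked example

```r
library(hubrank)

# a synthetic population: 50 subjects, 200 nodes (25 parcels/hemisphere x 4
# ROIs), multiplicative weight noise and edge flips around a shared
# hub-bearing, mirror-symmetric base connectome
pop <- generate_population(population_spec(n_subjects = 50, seed = 1))

# the worked ranking example: degree values -> ranking vector
rank_vector(c(50, 20, 30, 40, 10))
#> [1] 1 4 3 2 5
spearman_rank(c(1, 4, 3, 2, 5), c(1, 2, 3, 4, 5))
#> [1] 0.6

# ATM vs MTA representation power
cmp <- compare_aggregation(pop, measures = c("degree", "strength", "hubness"))
glance(cmp)
#>    measure method mean_correlation
#> 1   degree    ATM        0.2449413
#> 2   degree    MTA        0.9095326
#> 3 strength    ATM        0.9035027
#> 4 strength    MTA        0.9035816
#> 5  hubness    ATM        0.4694840
#> 6  hubness    MTA        0.9104007
```

MTA represents the population far better than ATM for topology-driven
measures (0.91 vs 0.24 for degree here): averaging matrices unions the
subjects' edge sets, which destroys the degree ordering, while averaging
per-subject ranks converges on the shared architecture. The two methods tie
for strength, where weight averaging preserves the ordering.

```r
# how many subjects does a representative sample need?
ssc <- sample_size_curve(pop, sizes = c(1, 5, 20, 50), seed = 1)
glance(ssc)
#>   size mean_correlation min_correlation max_correlation
#> 1    1        0.9104592       0.8826261       0.9326090
#> 2    5        0.9795477       0.9711054       0.9855324
#> 3   20        0.9958791       0.9945807       0.9972452
#> 4   50        1.0000000       1.0000000       1.0000000
autoplot(ssc)

# hemispheric asymmetry on this mirror-symmetric population: a clean null
glance(hemispheric_asymmetry(parcel_rank_table(pop)))
#>   n_pairs left_dominant right_dominant symmetric margin alpha     test
#> 1      25             0              0        25   0.05  0.01 wilcoxon
```

The correlation rises steeply and plateaus near 50 subjects (1.0 here
because the sample *is* the population at size 50); the asymmetry test
classifies all 25 homologous parcel pairs symmetric, as it should on a
mirror-symmetric population.

Result objects are tibbles with `tidy()` / `glance()` methods and
`autoplot()` figures; matrices, streamline tables, label volumes and whole
populations read and write through `read_matrix()` / `write_matrix()` (TSV
or Matrix Market), `read_streamlines()`, `read_label_volume()` (NIfTI) and
`write_population()`. A command-line pipeline is installed at
`system.file("exec", "hubrank", package = "hubrank")` with subcommands
`simulate`, `subparcellate`, `build`, `measure`, `aggregate`, `sample-size`,
`hubs`, `asymmetry` and `heterogeneity`.

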