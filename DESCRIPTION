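Package: hubrank
Title: Rank-Based Group-Level Hubness Analysis of Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for group-level, ranking-based hub analysis of structural
    brain connectivity networks. Builds weighted connectomes from streamline
    endpoint tables, sub-parcellates atlas label volumes into similar-size
    regions of interest by k-means on voxel coordinates, computes five
    node-level graph measures (degree, strength, coreness, betweenness,
    closeness) and a composite hubness rank, and compares two group
    aggregation strategies: aggregate-then-measure (ATM, average the
    connectivity matrices first) and measure-then-aggregate (MTA, rank each
    subject first and average the rankings). Includes downstream analyses
    (sample-size curves, consistent-hub identification, hemispheric asymmetry
    testing, intraparcel heterogeneity) and a synthetic connectome population
    generator so every stage can be exercised without access to large
    diffusion MRI datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
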