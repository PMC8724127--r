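# ggplot2 autoplot methods for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ATM vs MTA representation-power comparison
#'
#' Box plots of per-subject representation correlations for each measure and
#' aggregation method.
#'
#' @param object An `aggregation_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aggregation_comparison <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$measure, y = .data$correlation, fill = .data$method)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = NULL, y = "Spearman correlation with individual rankings",
      fill = "Aggregation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sample-size curve
#'
#' Mean replicate correlation against sample size (log scale) with the
#' replicate range as a ribbon.
#'
#' @param object A `sample_size_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_size_curve <- function(object, ...) {
  s <- glance(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = .data$mean_correlation)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_correlation, ymax = .data$max_correlation),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Sample size (subjects)",
      y = "Spearman correlation with population ranking"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a hemispheric asymmetry report
#'
#' Mean left-right rank difference per homologous pair, coloured by
#' classification; the dashed lines mark the decision margin.
#'
#' @param object An `asymmetry_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asymmetry_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$pair <- factor(
    paste(df$parcel_left, df$parcel_right, sep = "/"),
    levels = paste(df$parcel_left, df$parcel_right, sep = "/")[order(df$mean_diff)]
  )
  m <- attr(object, "margin") * attr(object, "n_units")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pair, y = .data$mean_diff,
    colour = .data$classification
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = c(-m, 0, m), linetype = c("dashed", "solid", "dashed")) +
    ggplot2::scale_colour_manual(values = c(
      "left-dominant" = "#c0392b",
      "right-dominant" = "#2980b9", "symmetric" = "#b7950b"
    )) +
    ggplot2::labs(
      x = "Homologous parcel pair",
      y = "Mean rank difference (left - right)",
      colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot intraparcel heterogeneity
#'
#' Box plots of group-level ROI hubness ranks within each of the most
#' heterogeneous parcels.
#'
#' @param object A `heterogeneity_report`.
#' @param top_n Number of parcels to show, ordered by rank IQR (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heterogeneity_report <- function(object, top_n = 10, ...) {
  roi <- attr(object, "roi_ranks")
  keep <- object |>
    tibble::as_tibble() |>
    dplyr::arrange(dplyr::desc(.data$iqr)) |>
    utils::head(top_n)
  roi <- roi[roi$parcel %in% keep$parcel, ]
  roi$parcel <- factor(roi$parcel, levels = keep$parcel)
  ggplot2::ggplot(roi, ggplot2::aes(x = .data$parcel, y = .data$rank)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Parcel", y = "Group-level ROI hubness rank (1 = top)") +
    ggplot2::theme_minimal()
}

#' Plot a measure intercorrelation matrix
#'
#' Heat map of the pairwise Spearman correlations between the six group-level
#' measure rankings.
#'
#' @param mat A 6 x 6 correlation matrix from [measure_intercorrelation()].
#' @return A ggplot object.
#' @export
plot_measure_intercorrelation <- function(mat) {
  df <- tibble::as_tibble(as.data.frame.table(mat, responseName = "correlation"))
  names(df)[1:2] <- c("measure_a", "measure_b")
  ggplot2::ggplot(df, ggplot2::aes(.data$measure_a, .data$measure_b,
    fill = .data$correlation
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$correlation)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b", midpoint = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r_s") +
    ggplot2::theme_minimal()
}
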