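#' Plot the PC1/PC2 score cloud with the fitted success path
#'
#' Conditions are coloured by strain, shaped by time point; failure-strain
#' rows are hollow by linetype of the path. The fitted total-least-squares
#' line is drawn dashed.
#'
#' @param object A [pca_trajectory()] model.
#' @param line A [fit_path()] line (fitted if omitted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_model <- function(object, line = NULL, ...) {
  line <- line %||% fit_path(object)
  df <- tidy(object)
  pcs <- colnames(object$scores)[line$pair]
  ggplot2::ggplot(df, ggplot2::aes(.data[[pcs[1]]], .data[[pcs[2]]])) +
    ggplot2::geom_abline(slope = line$slope, intercept = line$intercept,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$strain,
                                     shape = .data$timepoint), size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", pcs[1], 100 * object$variance_fraction[line$pair[1]]),
      y = sprintf("%s (%.0f%%)", pcs[2], 100 * object$variance_fraction[line$pair[2]]),
      title = "Transcriptional-change scores and fitted success path"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment report as a significance bar chart
#'
#' Bars show `-log10` of the Bonferroni-corrected p-value per set, faceted
#' by annotation kind, with the significance threshold marked.
#'
#' @param object An `enrichment_report` from [binomial_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_report <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.001
  df <- tidy(object) |>
    mutate(neglog = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$set, .data$neglog),
                                   .data$neglog, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "adjusted P"),
                  title = "Gene-set enrichment (binomial, Bonferroni)") +
    ggplot2::theme_minimal()
}

#' Plot cluster centroid profiles against growth rate
#'
#' One line per cluster centroid across the condition rows, ordered by
#' growth rate where defined; useful to eyeball which clusters track growth.
#'
#' @param object A [kmeans_profiles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_profiles <- function(object, ...) {
  cond <- object$conditions
  df <- as_tibble(object$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "condition",
                        values_to = "change") |>
    left_join(cond, by = "condition")
  df$condition <- factor(df$condition,
                         levels = cond$condition[order(cond$growth_rate)])
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$change,
                                   group = .data$cluster,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "condition (ordered by growth rate)",
                  y = "centroid change (log units)",
                  title = "K-means centroid profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot GFP-bias distributions of gated events
#'
#' Density of per-cell GFP bias (log scale) by condition, the standard view
#' for comparing rich-medium and starved populations.
#'
#' @param events_list Named list of gated event tables (names become
#'   condition labels).
#' @return A ggplot object.
#' @export
plot_bias_distributions <- function(events_list) {
  df <- purrr::map_dfr(names(events_list), function(nm) {
    tibble(condition = nm, bias = gfp_bias(events_list[[nm]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$bias, colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "GFP bias (GFP FI / RFP FI)", y = "density") +
    ggplot2::theme_minimal()
}
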