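# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_tile labs
#'   scale_fill_viridis_c theme_minimal
NULL

#' Plot a PCoA ordination
#'
#' @param object A `pcoa_ordination` from [pcoa_ordination()].
#' @param metadata Optional tibble with a `sample` column to join
#'   (e.g. habitat labels).
#' @param colour Name of a metadata column to colour points by.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_ordination
#' @export
autoplot.pcoa_ordination <- function(object, metadata = NULL,
                                     colour = NULL, ...) {
  pts <- as_tibble(object$points[, 1:2, drop = FALSE], rownames = "sample")
  if (!is.null(metadata)) pts <- left_join(pts, metadata, by = "sample")
  ve <- 100 * object$variance_explained
  p <- ggplot(pts, aes(x = .data$Axis1, y = .data$Axis2))
  if (!is.null(colour)) {
    p <- p + geom_point(aes(colour = .data[[colour]]), size = 3)
  } else {
    p <- p + geom_point(size = 3)
  }
  p +
    labs(
      x = sprintf("Axis 1 (%.1f%%)", ve[1]),
      y = sprintf("Axis 2 (%.1f%%)", if (length(ve) > 1) ve[2] else 0)
    ) +
    theme_minimal()
}

#' Plot collector curves
#'
#' Individual randomizations in grey, the mean curve on top.
#'
#' @param object A `collector_curve` from [collectors_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot collector_curve
#' @export
autoplot.collector_curve <- function(object, ...) {
  ggplot(object$curves,
         aes(x = .data$n_samples, y = .data$richness,
             group = .data$randomization)) +
    geom_line(alpha = 0.25, colour = "grey55") +
    geom_line(
      data = object$mean,
      aes(x = .data$n_samples, y = .data$mean_richness, group = 1),
      colour = "red", linewidth = 1
    ) +
    labs(x = "Samples", y = "Cumulative vOTU richness") +
    theme_minimal()
}

#' Abundance heat map
#'
#' Samples by vOTUs, log10-scaled fill; undetected cells are blank.
#'
#' @param abundance Samples-by-vOTUs abundance matrix (per-Gbp units).
#' @return A ggplot.
#' @export
plot_abundance_heatmap <- function(abundance) {
  long <- as_tibble(abundance, rownames = "sample") %>%
    tidyr::pivot_longer(-"sample", names_to = "votu",
                        values_to = "abundance") %>%
    mutate(log_abundance = ifelse(.data$abundance > 0,
                                  log10(.data$abundance), NA_real_))
  ggplot(long, aes(x = .data$votu, y = .data$sample,
                   fill = .data$log_abundance)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey92",
                         name = "log10 abundance\n(per Gbp)") +
    labs(x = "vOTU", y = "Virome") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
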