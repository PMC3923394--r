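#' Plot a metagene average binding profile
#'
#' Line plot of the averaged normalized coverage over the 100 segments of
#' a zone, the standard average-distribution display.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Segment (5' → 3')",
      y = "Mean normalized reads",
      title = sprintf("Metagene profile: %s (%d genes)",
                      attr(object, "zone"), attr(object, "n_genes"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the genomic distribution of peaks across zones
#'
#' Bar chart of peak counts per zone (promoter / gene body / downstream /
#' intergenic) from a [classify_peaks()] annotation table.
#'
#' @param annotations Output of [classify_peaks()].
#' @return A ggplot.
#' @export
plot_peak_distribution <- function(annotations) {
  lv <- c("promoter", "gene_body", "downstream", "intergenic")
  df <- annotations |>
    mutate(zone = factor(.data$zone, levels = lv)) |>
    dplyr::count(.data$zone, .drop = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Peaks",
                  title = "Peak distribution across genic zones") +
    ggplot2::theme_minimal()
}

#' Plot category over-representation
#'
#' Horizontal bar chart of fold over-representation per category, ordered
#' by significance.
#'
#' @param enrichment Output of [enrich_categories()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  df <- mutate(enrichment,
               category = stats::reorder(.data$category, -.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Fold over-representation", y = NULL) +
    ggplot2::theme_minimal()
}
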