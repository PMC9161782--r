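# ggplot2 figure builders for the standard result types.

#' Per-population density (or proportion) by disease stage
#'
#' Box-and-jitter panels per population, ROIs as points, with optional
#' significance stars from the pairwise stage comparisons.
#'
#' @param summaries Cohort summary tibble.
#' @param measure `"density"` or `"proportion"`.
#' @param populations Subset of populations to plot (default: all).
#' @param comparisons Optional pairwise-comparison tibble (with
#'   `population`, `group1`, `group2`, `stars`); significant pairs are
#'   listed in the panel subtitle.
#' @param stages Stage order on the x axis.
#' @return A ggplot object.
#' @export
plot_density_by_stage <- function(summaries,
                                  measure = c("density", "proportion"),
                                  populations = NULL, comparisons = NULL,
                                  stages = mihc_stages()) {
  measure <- match.arg(measure)
  df <- summaries
  if (!is.null(populations)) df <- df[df$population %in% populations, ]
  if (measure == "proportion") df <- df[df$proportion_defined, ]
  df$stage <- factor(df$stage, levels = stages)
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    sig <- comparisons %>%
      filter(.data$stars != "ns") %>%
      mutate(lab = paste0(.data$group1, "-", .data$group2, " ",
                          .data$stars)) %>%
      group_by(.data$population) %>%
      summarise(sig = paste(.data$lab, collapse = ", "), .groups = "drop")
    df <- left_join(df, sig, by = "population")
    df$panel <- ifelse(is.na(df$sig), df$population,
                       paste0(df$population, "\n", df$sig))
  } else {
    df$panel <- df$population
  }
  ylab <- if (measure == "density") "cells / mm²" else "proportion"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_bw(base_size = 9)
}

#' Heatmap of cluster mean marker profiles
#'
#' @param profiles Tibble from [cluster_profiles()].
#' @param markers Marker columns to show.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(profiles, markers = NULL) {
  if (is.null(markers)) {
    markers <- setdiff(names(profiles), c("group", "n_cells"))
  }
  long <- tidyr::pivot_longer(profiles, all_of(markers),
                              names_to = "marker", values_to = "intensity")
  long$marker <- factor(long$marker, levels = markers)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker,
                                     y = factor(.data$group),
                                     fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean\nintensity") +
    ggplot2::labs(x = NULL, y = "group") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Neighbourhood-enrichment heatmap
#'
#' Red/blue tile map of z-scores per (reference, target) pair; grey tiles
#' mark non-significant or non-evaluable pairs when a `class` column is
#' present. Faceted by stage when a `stage` column is present.
#'
#' @param enrichment Per-ROI or stage-aggregated enrichment tibble.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  df <- enrichment
  zcol <- if ("mean_z" %in% names(df)) "mean_z" else "z"
  if ("class" %in% names(df)) {
    df[[zcol]][df$class %in% c("ns", "not_evaluable")] <- NA
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$target,
                                        y = .data$reference,
                                        fill = .data[[zcol]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", midpoint = 0,
                                  na.value = "grey85", name = "z") +
    ggplot2::labs(x = "target (neighbour)", y = "reference") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("stage" %in% names(df)) p <- p + ggplot2::facet_wrap(~stage)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mihc_ssc <- function(object, ...) {
  plot_cluster_profiles(object$profiles, ...)
}

#' @export
autoplot.mihc_enrichment <- function(object, ...) {
  plot_enrichment(object)
}
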