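#' Isotope biplot of group means
#'
#' Mean +/- SD of 13C vs 15N enrichment (or raw delta values) per group,
#' the standard way mycoheterotrophy surveys display how far target
#' plants sit from their autotrophic references along both isotope axes.
#'
#' @param data Samples or enrichment records.
#' @param x,y Column names to plot (defaults `eps13C`, `eps15N`; pass
#'   `delta13C`/`delta15N` for raw values).
#' @return A ggplot object.
#' @export
plot_isotope_biplot <- function(data, x = "eps13C", y = "eps15N") {
  smry <- group_summary(data, cols = c(x, y))
  ggplot2::ggplot(smry, ggplot2::aes(
    x = .data[[paste0("mean_", x)]], y = .data[[paste0("mean_", y)]],
    colour = .data$group
  )) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[paste0("mean_", y)]] -
        dplyr::coalesce(.data[[paste0("sd_", y)]], 0),
      ymax = .data[[paste0("mean_", y)]] +
        dplyr::coalesce(.data[[paste0("sd_", y)]], 0)
    ), width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data[[paste0("mean_", x)]] -
        dplyr::coalesce(.data[[paste0("sd_", x)]], 0),
      xmax = .data[[paste0("mean_", x)]] +
        dplyr::coalesce(.data[[paste0("sd_", x)]], 0)
    ), height = 0) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = bquote(.(x) ~ "(‰)"), y = bquote(.(y) ~ "(‰)"),
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mixing-model result
#'
#' Group %Cdf means with SD error bars and the per-individual estimates
#' overlaid; dashed lines mark the 0 and 100 % end members.
#'
#' @param object A `mixing_result` from [mixing_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixing_result
#' @export
autoplot.mixing_result <- function(object, ...) {
  ind <- tidy(object)
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$group, y = .data$pcdf_mean
  )) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$pcdf_mean - dplyr::coalesce(.data$pcdf_sd, 0),
      ymax = .data$pcdf_mean + dplyr::coalesce(.data$pcdf_sd, 0)
    ), width = 0.2) +
    ggplot2::geom_jitter(
      data = ind, ggplot2::aes(x = .data$group, y = .data$pcdf),
      width = 0.08, alpha = 0.6, size = 1.5
    ) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Fungal-derived carbon (%)") +
    ggplot2::theme_minimal()
}

#' Stacked relative-abundance bars per group
#'
#' @param abundance Output of [relative_abundance()] (per group).
#' @return A ggplot object.
#' @export
plot_relative_abundance <- function(abundance) {
  unit <- if ("group" %in% names(abundance)) "group" else "sample_id"
  ggplot2::ggplot(abundance, ggplot2::aes(
    x = .data[[unit]], y = .data$percent, fill = .data$otu_id
  )) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = "OTU") +
    ggplot2::theme_minimal()
}
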