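#' @importFrom ggplot2 ggplot aes geom_boxplot geom_jitter geom_line geom_point
#'   geom_area geom_abline geom_col labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Box-and-jitter plot of an alpha-diversity index by group
#'
#' @param div Diversity tibble from [alpha_diversity()].
#' @param cohort Cohort tibble supplying `sample_id` and `group`.
#' @param index Column of `div` to plot (default `"shannon"`).
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(div, cohort, index = "shannon") {
  df <- dplyr::inner_join(div, cohort[c("sample_id", "group")], by = "sample_id")
  ggplot(df, aes(x = .data$group, y = .data[[index]], fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, size = 1.5) +
    labs(x = NULL, y = index) +
    theme_minimal() +
    ggplot2::guides(fill = "none")
}

#' Lorenz curves of per-sample abundance inequality
#'
#' @param x Wide relative-abundance tibble.
#' @param sample_ids Samples to draw (default all).
#' @return A ggplot object; the diagonal marks perfect evenness.
#' @export
plot_lorenz <- function(x, sample_ids = NULL) {
  m <- abund_mat(x)
  ids <- sample_ids %||% rownames(m)
  curves <- purrr::map(ids, function(s) {
    lc <- lorenz_gini(m[s, ])$curve
    lc$sample_id <- s
    lc
  }) |> dplyr::bind_rows()
  ggplot(curves, aes(x = .data$frac_species, y = .data$frac_abundance,
                     group = .data$sample_id, colour = .data$sample_id)) +
    geom_line(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "cumulative share of species", y = "cumulative share of abundance") +
    theme_minimal()
}

#' Stacked composition plot of the most abundant taxa
#'
#' @param rel Wide relative-abundance tibble (typically rank-aggregated).
#' @param top_n Number of taxa shown individually; the rest are pooled
#'   into `"other"` so every bar still sums to 100%.
#' @return A ggplot object.
#' @export
plot_taxa_composition <- function(rel, top_n = 12) {
  long <- tidyr::pivot_longer(rel, -"sample_id",
                              names_to = "taxon", values_to = "abundance")
  keep <- long |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(total = sum(.data$abundance), .groups = "drop") |>
    dplyr::slice_max(.data$total, n = top_n) |>
    dplyr::pull("taxon")
  long <- dplyr::mutate(long, taxon = ifelse(.data$taxon %in% keep, .data$taxon, "other"))
  ggplot(long, aes(x = .data$sample_id, y = .data$abundance, fill = .data$taxon)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "relative abundance (%)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Rarefaction curve plot
#'
#' @param curve Tibble from [rarefaction_curve()].
#' @param index `"mean_shannon"` or `"mean_richness"`.
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(curve, index = "mean_shannon") {
  ggplot(curve, aes(x = .data$depth, y = .data[[index]],
                    group = .data$sample_id, colour = .data$sample_id)) +
    geom_line(alpha = 0.7) +
    labs(x = "subsampled counts", y = index) +
    theme_minimal()
}

#' @describeIn pca_scores Score plot of the first two components.
#' @param object An `mgs_pca` object.
#' @param groups Optional group labels aligned with the scored samples.
#' @param ... Unused.
#' @method autoplot mgs_pca
#' @export
autoplot.mgs_pca <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) df$group <- groups
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2)) + theme_minimal() +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]))
  if (is.null(groups)) p + geom_point(size = 2)
  else p + geom_point(aes(colour = .data$group), size = 2)
}
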