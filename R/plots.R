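# ggplot2 visualizations for the main result types.

#' Plot read-class composition
#'
#' @param composition A `ccl_composition` from [composition_summary()].
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition$classes,
                  ggplot2::aes(x = stats::reorder(.data$class, -.data$fraction),
                               y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of reads",
                  title = "Read-class composition") +
    ggplot2::theme_minimal()
}

#' Plot seed-match density around the ligation site
#'
#' @param density Tibble from [seed_match_density()].
#' @return A ggplot.
#' @export
plot_seed_density <- function(density) {
  long <- tidyr::pivot_longer(density, c("real", "shuffled"),
                              names_to = "set", values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(.data$offset, .data$density,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(real = "firebrick",
                                           shuffled = "grey50")) +
    ggplot2::labs(x = "offset from ligation site (nt)",
                  y = "seed matches per chimera",
                  title = "Canonical seed-match density") +
    ggplot2::theme_minimal()
}

#' Plot cumulative fold-change distributions
#'
#' @param x A `ccl_cdf` from [cdf_compare()].
#' @return A ggplot.
#' @export
plot_cdf <- function(x) {
  ggplot2::ggplot(x$curves, ggplot2::aes(.data$log2fc, .data$cdf,
                                         color = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = "cumulative fraction",
                  subtitle = sprintf("KS D = %.3f, p = %.3g", x$statistic,
                                     x$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ccl_cdf <- function(object, ...) plot_cdf(object)

#' Heatmap of motif usage across miRNA positions and time points
#'
#' @param usage A `ccl_usage` from [usage_by_timepoint()] (or its `usage`
#'   tibble).
#' @param mirna Optional miRNA id to restrict to.
#' @return A ggplot.
#' @export
plot_motif_usage <- function(usage, mirna = NULL) {
  u <- if (inherits(usage, "ccl_usage")) usage$usage else usage
  if (!is.null(mirna)) u <- u[u$mirna_id %in% mirna, ]
  ggplot2::ggplot(u, ggplot2::aes(.data$timepoint, .data$position,
                                  fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~mirna_id) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(y = "miRNA position (5'->3')", x = NULL,
                  fill = "proportion of targets") +
    ggplot2::theme_minimal()
}

#' Plot SOM tile occupancy and mean profiles
#'
#' @param som A `ccl_som` from [som_fit()].
#' @return A ggplot of per-tile occupancy colored by the leading time point.
#' @export
plot_som <- function(som) {
  occ <- dplyr::count(som$tile_of, .data$tile_row, .data$tile_col)
  lead <- apply(som$tile_mean, 1, which.max)
  occ$leading <- factor(lead[(occ$tile_col - 1) * som$grid[1] + occ$tile_row])
  ggplot2::ggplot(occ, ggplot2::aes(.data$tile_col, .data$tile_row,
                                    fill = .data$leading,
                                    alpha = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "tile column", y = "tile row",
                  fill = "leading time point", alpha = "interactions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ccl_som <- function(object, ...) plot_som(object)

#' Heatmap of stage correlations
#'
#' @param r Correlation matrix from [stage_correlation()].
#' @return A ggplot.
#' @export
plot_stage_correlation <- function(r) {
  long <- tibble::as_tibble(r, rownames = "a") |>
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "r")
  long$a <- factor(long$a, levels = rownames(r))
  long$b <- factor(long$b, levels = rownames(r))
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
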