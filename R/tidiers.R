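# broom-style tidiers for fitted result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a SOM fit
#'
#' @param x A `ccl_som` object.
#' @param ... Unused.
#' @return Tibble of tile assignments (`interaction_id`, `tile`, `tile_row`,
#'   `tile_col`).
#' @export
tidy.ccl_som <- function(x, ...) x$tile_of

#' One-row summary of a SOM fit
#'
#' @param x A `ccl_som` object.
#' @param ... Unused.
#' @return Tibble with grid shape, epochs, quantization error, topographic
#'   ratio and seed.
#' @export
glance.ccl_som <- function(x, ...) {
  topo <- som_topographic_stat(x)
  tibble::tibble(grid_rows = x$grid[1], grid_cols = x$grid[2],
                 n = nrow(x$tile_of), epochs = x$epochs,
                 quantization_error = x$quantization_error,
                 topographic_ratio = unname(topo["ratio"]),
                 seed = x$seed)
}

#' One-row summary of an energy-gap test
#'
#' @param x A `ccl_energy_gap` object.
#' @param ... Unused.
#' @return Tibble with the median/mean gaps and permutation p-value.
#' @export
glance.ccl_energy_gap <- function(x, ...) {
  tibble::tibble(delta_median = x$delta_median, delta_mean = x$delta_mean,
                 p_mean = x$p_mean, n_real = x$n_real, n_null = x$n_null,
                 n_perm = x$n_perm)
}

#' Tidy the CDF curves of a fold-change comparison
#'
#' @param x A `ccl_cdf` object.
#' @param ... Unused.
#' @return The `curves` tibble.
#' @export
tidy.ccl_cdf <- function(x, ...) x$curves

#' One-row summary of a fold-change CDF comparison
#'
#' @param x A `ccl_cdf` object.
#' @param ... Unused.
#' @return Tibble with the KS statistic, p-value and set sizes.
#' @export
glance.ccl_cdf <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_a = x$n_a, n_b = x$n_b)
}
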