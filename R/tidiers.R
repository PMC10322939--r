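#' Tidy a metrics panel into one row per derived metric
#'
#' @param x A [metrics_panel()].
#' @param ... Unused.
#' @return A tibble `metric`, `log2_ratio`, `reason`, `pair_index`,
#'   `stratum`.
#' @method tidy metrics_panel
#' @export
tidy.metrics_panel <- function(x, ...) {
  dplyr::mutate(x$derived, pair_index = x$pair_index,
                stratum = x$stratum %||% NA_character_)
}

#' One-row summary of a metrics panel: the seven region averages
#'
#' @param x A [metrics_panel()].
#' @param ... Unused.
#' @return A one-row tibble with columns `T_A`, `T_Af`, `T_B`, `T_Bf`,
#'   `T_C`, `T_D`, `T_E`, `n_pairs`, `pair_index`, `stratum`.
#' @method glance metrics_panel
#' @export
glance.metrics_panel <- function(x, ...) {
  tv <- stats::setNames(as.list(x$regions$value),
                        paste0("T_", x$regions$label))
  tibble::as_tibble(c(tv, list(n_pairs = x$n_pairs,
                               pair_index = x$pair_index,
                               stratum = x$stratum %||% NA_character_)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Heatmap of a two-dimensional signal density
#'
#' Undefined cells are left blank; the fill is the signal density on a log2
#' scale (values are relative to the genome-wide mean after normalization).
#'
#' @param object A [density_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = log2(.data$value + 1e-6))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 density") +
    ggplot2::labs(
      x = "x = z - z_U (bp from upstream TSS)",
      y = "y = z - z_D (bp from downstream TSS)",
      title = sprintf("2D signal density (pair index %s, stratum %s)",
                      attr(object, "pair_index") %||% NA,
                      attr(object, "stratum") %||% NA)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of the derived interdependence metrics
#'
#' @param object A [metrics_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_panel
#' @export
autoplot.metrics_panel <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$log2_ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$log2_ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 ratio",
                  title = sprintf("TSS interdependence metrics (pair index %s)",
                                  object$pair_index)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Pair-index summary plot in the style of the cross-experiment panels
#'
#' @param summary Tibble from [pair_index_summary()].
#' @param metrics Metrics to show (default all present).
#' @return A ggplot object.
#' @export
plot_pair_summary <- function(summary, metrics = unique(summary$metric)) {
  df <- dplyr::filter(summary, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_group,
                                   y = .data$log2_value,
                                   group = .data$stratum,
                                   colour = .data$stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "TSS pair", y = "log2 value") +
    ggplot2::theme_minimal()
}
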