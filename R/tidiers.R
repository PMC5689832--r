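#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an all-pairs co-occurrence analysis
#'
#' @param x A `pa_cooccurrence` object.
#' @param ... Unused.
#' @return The per-pair result tibble (one row per unordered taxon pair).
#' @method tidy pa_cooccurrence
#' @export
tidy.pa_cooccurrence <- function(x, ...) x$pairs

#' One-row summary of an all-pairs co-occurrence analysis
#'
#' @param x A `pa_cooccurrence` object.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, per-test alpha, and the
#'   concordance counts/fractions of [concordance_summary()].
#' @method glance pa_cooccurrence
#' @export
glance.pa_cooccurrence <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_taxa = x$n_taxa, n_sites = x$n_sites,
           family_alpha = x$config$family_alpha,
           alpha_per_test = x$alpha_per_test),
    concordance_summary(x))
}

#' Plot the Jaccard-versus-phi comparison of an all-pairs analysis
#'
#' Scatter of Jaccard's index against the phi coefficient for every
#' non-degenerate pair, colored by which metric(s) call the pair
#' significant at the familywise-corrected level.
#'
#' @param object A `pa_cooccurrence` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_cooccurrence
#' @export
autoplot.pa_cooccurrence <- function(object, ...) {
  p <- object$pairs |>
    dplyr::filter(!.data$degenerate) |>
    dplyr::mutate(significance = dplyr::case_when(
      .data$sig_j & .data$sig_r ~ "both",
      .data$sig_j ~ "J only",
      .data$sig_r ~ "r only",
      TRUE ~ "neither"))
  ggplot2::ggplot(p, ggplot2::aes(x = .data$r, y = .data$j,
                                  colour = .data$significance)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "phi coefficient (r)", y = "Jaccard's index (J)",
                  colour = "significant for") +
    ggplot2::theme_minimal()
}

#' Plot a prevalence-binned significance grid
#'
#' Heatmap of one layer of the grid produced by [prevalence_grid()].
#'
#' @param grid A tibble from [prevalence_grid()].
#' @param layer One of `"n_total"`, `"n_sig_j"`, `"n_sig_r"`, `"diff_sig"`.
#' @return A ggplot object.
#' @export
plot_prevalence_grid <- function(grid, layer = c("diff_sig", "n_total",
                                                 "n_sig_j", "n_sig_r")) {
  layer <- match.arg(layer)
  g <- dplyr::filter(grid, !.data$empty)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$bin_lo_max, y = .data$bin_lo_min,
                                  fill = .data[[layer]])) +
    ggplot2::geom_tile(width = g$bin_hi_max - g$bin_lo_max,
                       height = g$bin_hi_min - g$bin_lo_min) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "prevalence of the commoner member",
                  y = "prevalence of the rarer member", fill = layer) +
    ggplot2::theme_minimal()
}

#' Plot a null distribution with an optional observed count
#'
#' @param dist A `null_distribution`.
#' @param x_obs Optional observed co-occurrence count to mark.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(dist, x_obs = NULL) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$x, y = .data$prob)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "co-occurrence count", y = "probability",
                  title = attr(dist, "source")) +
    ggplot2::theme_minimal()
  if (!is.null(x_obs)) {
    p <- p + ggplot2::geom_vline(xintercept = x_obs, colour = "red",
                                 linetype = "dashed")
  }
  p
}
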