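#' Plot an EVPPI grid as a heatmap
#'
#' Tile plot of the proportion of each output's variance attributable to each
#' parameter, the standard display for parameter-importance in
#' evidence-synthesis sensitivity analysis.
#'
#' @param grid Output of [evppi_grid()].
#' @return A ggplot object.
#' @export
plot_evppi_grid <- function(grid) {
  stopifnot(all(c("output", "parameter", "proportion") %in% names(grid)))
  ggplot2::ggplot(grid, ggplot2::aes(
    x = factor(parameter, levels = unique(parameter)),
    y = factor(output, levels = rev(unique(output))),
    fill = pmin(pmax(proportion, 0), 1)
  )) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_viridis_c(name = "EVPPI /\nvar(output)", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an EVSI curve
#'
#' Expected posterior standard deviation remaining after a future study,
#' against its sample size.
#'
#' @param object Output of [evsi_curve()].
#' @param ... Unused.
#' @export
autoplot.voi_evsi_curve <- function(object, ...) {
  plot_evsi_curve(object)
}

#' @rdname autoplot.voi_evsi_curve
#' @param curve Output of [evsi_curve()] (columns `n`, `residual_sd`).
#' @export
plot_evsi_curve <- function(curve) {
  stopifnot(all(c("n", "residual_sd") %in% names(curve)))
  ggplot2::ggplot(curve, ggplot2::aes(n, residual_sd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "future sample size n",
      y = "expected SD remaining after study"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an expected-net-benefit-of-sampling curve
#'
#' Expected benefit, cost, and net benefit against sample size, with the
#' optimal size marked.
#'
#' @param object A `voi_enbs` table from [enbs_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voi_enbs <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("expected_benefit", "cost", "net_benefit"),
    names_to = "term", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(n, value, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "n_star"), linetype = "dotted") +
    ggplot2::labs(x = "sample size n", y = "currency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
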