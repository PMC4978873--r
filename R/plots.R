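#' Plot current service availability by village
#'
#' Stacked bars of landscape availability per village with the contribution
#' of each woodland type, error bars showing the 95% confidence interval of
#' the total; one panel per service (free y scales, since biomass and
#' stem-count services live on different scales).
#'
#' @param object A `service_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.service_estimates <- function(object, ...) {
  by_type <- object |>
    dplyr::select("village", "service", "by_type") |>
    tidyr::unnest("by_type")
  totals <- dplyr::select(object, "village", "service", "value", "ci_lo", "ci_hi")
  ggplot2::ggplot(by_type, ggplot2::aes(x = .data$village, y = .data$contribution,
                                        fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(data = totals,
                           ggplot2::aes(x = .data$village, ymin = pmax(.data$ci_lo, 0),
                                        ymax = .data$ci_hi),
                           inherit.aes = FALSE, width = 0.3) +
    ggplot2::facet_wrap(~service, scales = "free_y") +
    ggplot2::labs(x = "village", y = "availability (service units per landscape)",
                  fill = "woodland type") +
    ggplot2::theme_minimal()
}

#' Plot scenario percent changes
#'
#' Point-and-interval display of the percent change in each service under
#' the counterfactual charcoal scenarios, with 95% confidence intervals and
#' a zero reference line; one panel per service.
#'
#' @param object A `scenario_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$village, y = .data$pct_change,
                                       colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~service, scales = "free_y") +
    ggplot2::labs(x = "village", y = "change from current (%)",
                  colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot the grass-potential envelope
#'
#' Observed grass biomass against stem density with the fitted upper
#' envelope overlaid.
#'
#' @param object A `grass_envelope`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grass_envelope <- function(object, ...) {
  grid <- tibble::tibble(density = seq(object$range[1], object$range[2],
                                       length.out = 100))
  grid$potential <- as.numeric(predict(object, grid$density))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$density, y = .data$grass)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$potential), colour = "forestgreen") +
    ggplot2::labs(x = "stem density (stems/ha)",
                  y = "dry grass biomass (Mg/ha)",
                  title = sprintf("Upper envelope (%s, q = %.2f)",
                                  object$form, object$quantile)) +
    ggplot2::theme_minimal()
}

#' Plot the Calinski-Harabasz curve of a typology
#'
#' CH criterion against the number of clusters, with the selected k marked.
#'
#' @param object A `woodland_typology`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.woodland_typology <- function(object, ...) {
  ggplot2::ggplot(object$ch_scores, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "red") +
    ggplot2::labs(x = "number of woodland types (k)",
                  y = "Calinski-Harabasz criterion") +
    ggplot2::theme_minimal()
}
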