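#' Tidy a fitted grass envelope
#'
#' @param x A `grass_envelope`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.grass_envelope <- function(x, ...) {
  terms <- if (x$form == "linear") c("(Intercept)", "density") else c("log_intercept", "density")
  tibble::tibble(term = terms, estimate = unname(x$coef))
}

#' @rdname tidy.grass_envelope
#' @return For `glance()`: a one-row summary with the form, quantile level,
#'   number of plots and fitted density range.
#' @export
glance.grass_envelope <- function(x, ...) {
  tibble::tibble(form = x$form, quantile = x$quantile,
                 n_plots = nrow(x$data),
                 density_min = x$range[1], density_max = x$range[2])
}

#' Tidy a woodland typology
#'
#' @param x A `woodland_typology`.
#' @param ... Unused.
#' @return One row per plot: `plot_id`, `cluster`.
#' @export
tidy.woodland_typology <- function(x, ...) {
  tibble::tibble(plot_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname tidy.woodland_typology
#' @return For `glance()`: one row with the selected `k`, the maximal
#'   Calinski-Harabasz score and the number of plots.
#' @export
glance.woodland_typology <- function(x, ...) {
  tibble::tibble(k = x$k, ch_max = max(x$ch_scores$ch),
                 n_plots = length(x$labels))
}
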