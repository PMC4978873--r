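#' Per-plot availability of one tree-based service
#'
#' Ecological production function at plot level: for biomass services
#' (charcoal, firewood, construction) the summed allometric biomass of live,
#' uncut stems of linked species inside the service's DBH band, per hectare;
#' for density services (food, medicine) the count of such stems per
#' hectare. Cut or standing-dead stems provide no standing service.
#'
#' @param stems,plots Inventory tables.
#' @param links A `service_links` table.
#' @param service One of charcoal, firewood, construction, food, medicine.
#' @param allometry,taper Inventory configuration.
#' @return Tibble `plot_id`, `village`, `service`, `value` (per-ha units:
#'   Mg C ha^-1 for biomass services, stems ha^-1 for density services).
#' @export
plot_service <- function(stems, plots, links, service,
                         allometry = default_allometry(),
                         taper = default_taper()) {
  if (!service %in% tree_services()) {
    rlang::abort(sprintf("unknown tree service '%s'", service),
                 class = "mopane_domain_error")
  }
  sp <- service_species(links, service)
  band <- service_band(links, service)
  metric <- unique(links$metric[links$service == service])

  linked <- live_intact(stems) |>
    dplyr::mutate(dbh = correct_dbh(.data$diameter, .data$pom, taper)) |>
    dplyr::filter(.data$species %in% sp,
                  .data$dbh >= band[["min"]], .data$dbh <= band[["max"]])
  per_plot <- if (metric == "biomass") {
    linked |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::summarise(raw = sum(stem_agb(.data$dbh, allometry)), .groups = "drop")
  } else {
    linked |> dplyr::count(.data$plot_id, name = "raw")
  }
  plots |>
    dplyr::mutate(area_ha = plot_area_ha(.data$radius_m)) |>
    dplyr::select("plot_id", "village", "area_ha") |>
    dplyr::left_join(per_plot, by = "plot_id") |>
    dplyr::mutate(service = service,
                  value = dplyr::coalesce(.data$raw, 0) / .data$area_ha) |>
    dplyr::select("plot_id", "village", "service", "value")
}

#' Fit the grass-potential upper envelope
#'
#' Grass services cannot be tied to grass species, so maximum potential grass
#' biomass is modelled as an upper envelope of observed grass biomass against
#' stem density: a quantile (pinball-loss) fit at the configured level
#' (default 0.9), linear by default with an exponential-decay alternative.
#' Predictions are clamped at zero and, outside the fitted density range, at
#' the boundary value.
#'
#' @param density Per-plot stem density (stems ha^-1).
#' @param grass Per-plot dry grass biomass (Mg ha^-1); `NA` (burnt plots)
#'   dropped.
#' @param quantile Envelope level in (0, 1).
#' @param form `"linear"` (`b0 + b1 * density`) or `"exponential"`
#'   (`exp(c0 + c1 * density)`).
#' @return A `grass_envelope` object with `coef`, `quantile`, `form`,
#'   `range`, and the fitting data.
#' @export
fit_grass_envelope <- function(density, grass, quantile = 0.9,
                               form = c("linear", "exponential")) {
  form <- match.arg(form)
  keep <- !is.na(density) & !is.na(grass)
  density <- density[keep]; grass <- grass[keep]
  if (length(density) < 10) {
    rlang::abort("need at least 10 unburnt plots to fit the grass envelope",
                 class = "mopane_domain_error")
  }
  if (all(grass == 0)) {
    rlang::warn("all grass observations are zero; returning a zero envelope")
    out <- structure(list(coef = c(0, 0), quantile = quantile, form = "linear",
                          range = range(density),
                          data = tibble::tibble(density = density, grass = grass)),
                     class = "grass_envelope")
    return(out)
  }
  pinball <- function(resid) sum(resid * (quantile - (resid < 0)))
  predict_raw <- function(par, x) {
    if (form == "linear") par[1] + par[2] * x else exp(par[1] + par[2] * x)
  }
  loss <- function(par) pinball(grass - predict_raw(par, density))
  init <- coef(lm(grass ~ density))
  if (form == "exponential") {
    init <- coef(lm(log(pmax(grass, 1e-6)) ~ density))
  }
  fit <- optim(unname(init), loss, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  structure(list(coef = fit$par, quantile = quantile, form = form,
                 range = range(density),
                 data = tibble::tibble(density = density, grass = grass)),
            class = "grass_envelope")
}

#' Predict maximum potential grass biomass
#'
#' @param object A `grass_envelope`.
#' @param density Stem densities to predict at; values outside the fitted
#'   range are clamped to the boundary (and flagged in the `"extrapolated"`
#'   attribute).
#' @param ... Unused.
#' @return Predicted potential grass biomass (Mg ha^-1), clamped at zero.
#' @export
predict.grass_envelope <- function(object, density, ...) {
  extrapolated <- density < object$range[1] | density > object$range[2]
  x <- pmin(pmax(density, object$range[1]), object$range[2])
  raw <- if (object$form == "linear") {
    object$coef[1] + object$coef[2] * x
  } else {
    exp(object$coef[1] + object$coef[2] * x)
  }
  out <- pmax(raw, 0)
  attr(out, "extrapolated") <- extrapolated
  out
}

#' @export
print.grass_envelope <- function(x, ...) {
  cat(sprintf("<grass_envelope> %s fit at q = %.2f: (%.4g, %.4g) over density [%.0f, %.0f]\n",
              x$form, x$quantile, x$coef[1], x$coef[2], x$range[1], x$range[2]))
  invisible(x)
}

#' Per-plot availability of every service
#'
#' Runs [plot_service()] for the five tree services and the grass envelope
#' for the grass service (potential grass at the plot's live stem density),
#' returning one long table ready for class amalgamation.
#'
#' @param stems,plots Inventory tables.
#' @param links Service-link table.
#' @param envelope A fitted [fit_grass_envelope()]; when `NULL` the grass
#'   service is omitted.
#' @param allometry,taper Inventory configuration.
#' @return Long tibble `plot_id`, `village`, `service`, `value`.
#' @export
plot_services <- function(stems, plots, links, envelope = NULL,
                          allometry = default_allometry(),
                          taper = default_taper()) {
  out <- purrr::map(tree_services(), function(svc) {
    plot_service(stems, plots, links, svc, allometry, taper)
  }) |> purrr::list_rbind()
  if (!is.null(envelope)) {
    structure_tbl <- plot_structure(stems, plots, allometry, taper)
    grass <- structure_tbl |>
      dplyr::mutate(service = "grass",
                    value = as.numeric(predict(envelope, .data$stem_density))) |>
      dplyr::select("plot_id", "village", "service", "value")
    out <- dplyr::bind_rows(out, grass)
  }
  out
}

#' Upscale per-type service parameters to village landscapes
#'
#' Area-weighted totals: for each village and service the landscape value is
#' `sum_type area * fraction_type * mean_type` using the chronosequence-class
#' parameters of the village's class, with standard errors propagated
#' assuming independence, `se = sqrt(sum (area * fraction * se_type)^2)`, and
#' 95% confidence intervals `value +/- 1.96 se`. Types whose SE was
#' suppressed (n < 4) contribute no error term; the output flags such
#' villages via `se_complete`.
#'
#' @param params Amalgamated parameters: tibble `class`, `type`, `service`,
#'   `mean`, `se`, `n` (service values per ha).
#' @param landcover Long land-cover table `village`, `type`, `fraction`.
#' @param class_map Tibble `village`, `class`.
#' @param area_ha Village sample area in hectares, see [village_area_ha()].
#' @return A `service_estimates` tibble: `village`, `service`, `value`,
#'   `se`, `ci_lo`, `ci_hi`, `se_complete`, and a `by_type` list-column of
#'   per-type contributions.
#' @export
village_totals <- function(params, landcover, class_map,
                           area_ha = village_area_ha()) {
  cover <- landcover |>
    dplyr::filter(.data$fraction > 0) |>
    dplyr::left_join(class_map, by = "village")
  if (any(is.na(cover$class))) {
    rlang::abort("every village needs a chronosequence class",
                 class = "mopane_validation_error")
  }
  joined <- cover |>
    dplyr::cross_join(dplyr::distinct(params, .data$service)) |>
    dplyr::left_join(params, by = c("class", "type", "service"))
  gaps <- joined |> dplyr::filter(is.na(.data$mean))
  if (nrow(gaps)) {
    rlang::abort(paste0(
      "no amalgamated parameter for (class, type, service): ",
      paste(sprintf("(%s, %s, %s)", gaps$class, gaps$type, gaps$service) |> unique() |> head(10),
            collapse = "; ")),
      class = "mopane_validation_error")
  }
  out <- joined |>
    dplyr::mutate(
      contribution = area_ha * .data$fraction * .data$mean,
      var_term = (area_ha * .data$fraction * dplyr::coalesce(.data$se, 0))^2,
      se_known = !is.na(.data$se)
    ) |>
    dplyr::group_by(.data$village, .data$service) |>
    dplyr::summarise(
      value = sum(.data$contribution),
      se = sqrt(sum(.data$var_term)),
      se_complete = all(.data$se_known),
      by_type = list(tibble::tibble(type = type, contribution = contribution)),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_lo = .data$value - 1.96 * .data$se,
                  ci_hi = .data$value + 1.96 * .data$se)
  # Villages with no woodland cover at all still get explicit zero estimates.
  missing_villages <- setdiff(unique(landcover$village), out$village)
  if (length(missing_villages)) {
    zeros <- tidyr::expand_grid(village = missing_villages,
                                service = unique(params$service)) |>
      dplyr::mutate(value = 0, se = 0, se_complete = TRUE,
                    by_type = list(tibble::tibble(type = character(0),
                                                  contribution = numeric(0))),
                    ci_lo = 0, ci_hi = 0)
    out <- dplyr::bind_rows(out, zeros)
  }
  class(out) <- c("service_estimates", class(out))
  out
}

#' Monte-Carlo check of the propagated landscape standard error
#'
#' Resamples each (type, service) per-ha mean from Normal(mean, se),
#' recomputes the landscape total and returns the empirical SD — the oracle
#' the closed-form propagation is tested against.
#'
#' @inheritParams village_totals
#' @param village,service Which estimate to check.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Seed.
#' @return Empirical SE of the landscape total.
#' @export
village_total_se_mc <- function(params, landcover, class_map, village, service,
                                area_ha = village_area_ha(),
                                n_draws = 1e5, seed = 1) {
  cls <- class_map$class[class_map$village == village]
  cover <- landcover |>
    dplyr::filter(.data$village == !!village, .data$fraction > 0)
  p <- params |>
    dplyr::filter(.data$class == cls, .data$service == !!service) |>
    dplyr::inner_join(cover, by = "type")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  draws <- vapply(seq_len(nrow(p)), function(i) {
    rnorm(n_draws, p$mean[i], dplyr::coalesce(p$se[i], 0)) * area_ha * p$fraction[i]
  }, numeric(n_draws))
  sd(rowSums(draws))
}
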