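#' The "no charcoal" counterfactual at stem level
#'
#' Models a woodland never harvested for charcoal: every cut stem of a
#' charcoal-linked species is restored as a live intact stem with DBH
#' reconstructed from its stump measurement via the taper model
#' ([reconstruct_stump_dbh()]). Other stems are untouched; stumps without a
#' recorded measurement height cannot be reconstructed and are left as-is
#' (their count is reported in the `"skipped"` attribute).
#'
#' @param stems Stem table.
#' @param links Service-link table (defines the charcoal species set).
#' @param taper Per-metre taper rate.
#' @return A new stem table; the input is not modified.
#' @export
apply_no_charcoal <- function(stems, links, taper = default_taper()) {
  charcoal_sp <- service_species(links, "charcoal")
  target <- stems$cut & stems$species %in% charcoal_sp
  reconstructable <- target & !is.na(stems$pom) & !is.na(stems$diameter)
  skipped <- sum(target & !reconstructable)
  if (skipped > 0) {
    rlang::inform(sprintf("%d charcoal stump(s) lacked a measurement height and were not restored",
                          skipped))
  }
  out <- stems
  if (any(reconstructable)) {
    dbh <- correct_dbh(out$diameter[reconstructable], out$pom[reconstructable], taper)
    out$diameter[reconstructable] <- dbh
    out$pom[reconstructable] <- 1.3
    out$alive[reconstructable] <- TRUE
    out$cut[reconstructable] <- FALSE
    out$stump_height[reconstructable] <- NA_real_
  }
  attr(out, "skipped") <- skipped
  out
}

#' The "total charcoal" counterfactual at stem level
#'
#' Models exhaustive selective harvest: every live intact stem of a
#' charcoal-linked species inside the charcoal DBH band is flagged cut
#' (left as a stump measured at 0.3 m, diameter inflated by the taper model
#' so the scenario round-trips through stump reconstruction). Non-charcoal
#' species are untouched — this is selective logging, not clear-felling.
#'
#' @inheritParams apply_no_charcoal
#' @return A new stem table; the input is not modified.
#' @export
apply_total_charcoal <- function(stems, links, taper = default_taper()) {
  charcoal_sp <- service_species(links, "charcoal")
  band <- service_band(links, "charcoal")
  dbh <- rep(NA_real_, nrow(stems))
  live <- stems$alive & !stems$cut
  dbh[live] <- correct_dbh(stems$diameter[live], stems$pom[live], taper)
  target <- live & stems$species %in% charcoal_sp &
    !is.na(dbh) & dbh >= band[["min"]] & dbh <= band[["max"]]
  out <- stems
  if (any(target)) {
    stump_h <- 0.3
    out$alive[target] <- FALSE
    out$cut[target] <- TRUE
    out$stump_height[target] <- stump_h
    out$pom[target] <- stump_h
    out$diameter[target] <- inflate_dbh_to_pom(dbh[target], stump_h, taper)
  }
  out
}

#' Percent change of a service estimate under a counterfactual
#'
#' Compares counterfactual landscape estimates with current ones:
#' `pct = 100 * (counterfactual - current) / current`, with a 95% CI from
#' first-order (delta-method) propagation of the two standard errors treated
#' as independent, or from Monte-Carlo resampling when `method = "mc"`.
#' Villages with a zero current estimate get `NA` percent change and are
#' reported by absolute change only.
#'
#' @param current,counterfactual `service_estimates` tibbles over the same
#'   villages and services.
#' @param scenario Label stored in the result (e.g. `"no_charcoal"`).
#' @param method `"delta"` (closed form) or `"mc"`.
#' @param n_draws,seed Monte-Carlo settings.
#' @return A `scenario_results` tibble: `village`, `service`, `scenario`,
#'   `pct_change`, `ci_lo`, `ci_hi`, `absolute_change`.
#' @export
scenario_change <- function(current, counterfactual, scenario = "scenario",
                            method = c("delta", "mc"),
                            n_draws = 1e5, seed = 1) {
  method <- match.arg(method)
  joined <- dplyr::inner_join(
    dplyr::select(current, "village", "service", cur = "value", cur_se = "se"),
    dplyr::select(counterfactual, "village", "service", cf = "value", cf_se = "se"),
    by = c("village", "service"))
  if (nrow(joined) != nrow(current)) {
    rlang::abort("current and counterfactual estimates must cover the same villages and services",
                 class = "mopane_validation_error")
  }
  if (method == "mc") {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  out <- joined |>
    dplyr::mutate(
      absolute_change = .data$cf - .data$cur,
      pct_change = dplyr::if_else(.data$cur > 0,
                                  100 * (.data$cf - .data$cur) / .data$cur,
                                  NA_real_)
    )
  if (method == "delta") {
    out <- out |>
      dplyr::mutate(
        se_pct = dplyr::if_else(
          .data$cur > 0,
          100 * sqrt((.data$cf_se / .data$cur)^2 +
                       (.data$cf * .data$cur_se / .data$cur^2)^2),
          NA_real_),
        ci_lo = .data$pct_change - 1.96 * .data$se_pct,
        ci_hi = .data$pct_change + 1.96 * .data$se_pct
      )
  } else {
    ci <- purrr::pmap(out[c("cur", "cur_se", "cf", "cf_se")],
                      function(cur, cur_se, cf, cf_se) {
      if (cur <= 0) return(c(NA_real_, NA_real_))
      cur_d <- rnorm(n_draws, cur, cur_se)
      cf_d <- rnorm(n_draws, cf, cf_se)
      pct <- 100 * (cf_d - cur_d) / cur_d
      quantile(pct[is.finite(pct)], c(0.025, 0.975), names = FALSE)
    })
    out$ci_lo <- purrr::map_dbl(ci, 1)
    out$ci_hi <- purrr::map_dbl(ci, 2)
  }
  out <- out |>
    dplyr::mutate(scenario = scenario) |>
    dplyr::select("village", "service", "scenario", "pct_change",
                  "ci_lo", "ci_hi", "absolute_change")
  class(out) <- c("scenario_results", class(out))
  out
}
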