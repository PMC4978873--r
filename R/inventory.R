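#' Correct a diameter measured off breast height to DBH
#'
#' Stems measured below (or above) the standard 1.3 m point of measurement
#' are corrected with a linear taper model:
#' `d(1.3) = d(pom) * (1 - taper * (1.3 - pom))`, clamped at zero. The model
#' is the identity at pom = 1.3 and strictly monotone in the measured
#' diameter.
#'
#' @param diameter Measured diameter in cm (vectorised).
#' @param pom Point of measurement in m.
#' @param taper Per-metre taper rate, see [default_taper()].
#' @return Estimated DBH in cm.
#' @export
#' @examples
#' correct_dbh(10, 1.3)        # identity
#' correct_dbh(10, 0.3, 0.02)  # 9.8
correct_dbh <- function(diameter, pom, taper = default_taper()) {
  if (any(diameter <= 0) || any(pom <= 0)) {
    rlang::abort("diameter and pom must be positive", class = "mopane_domain_error")
  }
  pmax(diameter * (1 - taper * (1.3 - pom)), 0)
}

#' Per-stem above-ground biomass from DBH
#'
#' Power-law allometry `AGB = a * DBH^b` (Mg C per stem with the default
#' coefficients).
#'
#' @param dbh DBH in cm (vectorised).
#' @param coeffs Allometry list, see [default_allometry()].
#' @return Biomass per stem in the allometry's units.
#' @export
stem_agb <- function(dbh, coeffs = default_allometry()) {
  if (any(dbh <= 0)) {
    rlang::abort("dbh must be positive", class = "mopane_domain_error")
  }
  if (!identical(coeffs$form, "power")) {
    rlang::abort(sprintf("unknown allometry form '%s'", coeffs$form),
                 class = "mopane_domain_error")
  }
  coeffs$a * dbh^coeffs$b
}

#' Reconstruct the DBH of a cut stem from its stump measurement
#'
#' Projects a stump diameter measured at height `pom` (below 1.3 m) to an
#' estimated DBH using the same linear taper model as [correct_dbh()], so a
#' stump generated from a known DBH reconstructs it exactly. Stems without a
#' recorded stump measurement height return `NA` with a warning and are
#' excluded from scenario gains.
#'
#' @param diameter Stump diameter in cm (vectorised).
#' @param pom Stump measurement height in m; may contain `NA`.
#' @param taper Per-metre taper rate.
#' @return Estimated DBH in cm (`NA` where the measurement height is missing).
#' @export
reconstruct_stump_dbh <- function(diameter, pom, taper = default_taper()) {
  missing <- is.na(pom) | is.na(diameter)
  if (any(missing)) {
    rlang::warn(sprintf("%d stump(s) without a measurement height skipped", sum(missing)))
  }
  out <- rep(NA_real_, length(diameter))
  if (any(!missing)) {
    out[!missing] <- correct_dbh(diameter[!missing], pom[!missing], taper)
  }
  out
}

live_intact <- function(stems) {
  dplyr::filter(stems, .data$alive, !.data$cut)
}

#' Per-plot woodland structure
#'
#' Computes, for every plot, the live-stem density (stems ha^-1),
#' above-ground woody biomass (Mg C ha^-1, taper-corrected DBH through the
#' allometry), species richness of live stems, and Pielou evenness of the
#' per-species biomass shares (Shannon H / ln richness, defined as 1 when
#' richness <= 1). Only live, uncut stems count; standing dead stems and
#' stumps are excluded.
#'
#' @param stems Stem table (`plot_id`, `species`, `diameter`, `pom`, `alive`,
#'   `cut`).
#' @param plots Plot table (`plot_id`, `village`, `radius_m`, `burnt`).
#' @param allometry,taper Allometry and taper configuration.
#' @return A tibble with one row per plot: `plot_id`, `village`, `area_ha`,
#'   `stem_density`, `agb`, `richness`, `evenness`, `n_cut`.
#' @export
plot_structure <- function(stems, plots, allometry = default_allometry(),
                           taper = default_taper()) {
  if (any(plots$radius_m <= 0)) {
    rlang::abort("plot radius must be positive", class = "mopane_domain_error")
  }
  live <- live_intact(stems) |>
    dplyr::mutate(dbh = correct_dbh(.data$diameter, .data$pom, taper),
                  agb_stem = stem_agb(.data$dbh, allometry))
  per_plot <- live |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      n_live = dplyr::n(),
      agb_sum = sum(.data$agb_stem),
      richness = dplyr::n_distinct(.data$species),
      evenness = pielou_evenness(.data$agb_stem, .data$species),
      .groups = "drop"
    )
  n_cut <- stems |>
    dplyr::filter(.data$cut) |>
    dplyr::count(.data$plot_id, name = "n_cut")
  plots |>
    dplyr::mutate(area_ha = plot_area_ha(.data$radius_m)) |>
    dplyr::left_join(per_plot, by = "plot_id") |>
    dplyr::left_join(n_cut, by = "plot_id") |>
    dplyr::mutate(
      n_live = dplyr::coalesce(.data$n_live, 0L),
      n_cut = dplyr::coalesce(.data$n_cut, 0L),
      agb_sum = dplyr::coalesce(.data$agb_sum, 0),
      richness = dplyr::coalesce(.data$richness, 0L),
      evenness = dplyr::coalesce(.data$evenness, 1),
      stem_density = .data$n_live / .data$area_ha,
      agb = .data$agb_sum / .data$area_ha
    ) |>
    dplyr::select("plot_id", "village", "area_ha", "n_live", "n_cut",
                  "stem_density", "agb", "richness", "evenness")
}

# Pielou's J on biomass shares: Shannon H over species AGB totals divided by
# ln(richness); 1 when one or zero species.
pielou_evenness <- function(agb_stem, species) {
  totals <- tapply(agb_stem, species, sum)
  totals <- totals[totals > 0]
  s <- length(totals)
  if (s <= 1) return(1)
  p <- totals / sum(totals)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Per-plot dry grass biomass
#'
#' Mean over the plot's quadrats of fresh mass times dry fraction, converted
#' from g m^-2 (1 m^2 quadrats) to Mg ha^-1 (factor 0.01). Recently burnt
#' plots are flagged and their grass value set to `NA`; they are excluded
#' from grass means downstream rather than failing.
#'
#' @param quadrats Quadrat table (`plot_id`, `fresh_g`, `dry_fraction`).
#' @param plots Plot table with `burnt`.
#' @return Tibble `plot_id`, `grass` (Mg ha^-1, `NA` when burnt),
#'   `grass_excluded`.
#' @export
grass_biomass <- function(quadrats, plots) {
  if (any(quadrats$fresh_g < 0)) {
    rlang::abort("quadrat masses must be non-negative", class = "mopane_domain_error")
  }
  per_plot <- quadrats |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(grass = mean(.data$fresh_g * .data$dry_fraction) * 0.01,
                     .groups = "drop")
  plots |>
    dplyr::select("plot_id", "burnt") |>
    dplyr::left_join(per_plot, by = "plot_id") |>
    dplyr::mutate(grass_excluded = .data$burnt,
                  grass = dplyr::if_else(.data$burnt, NA_real_, .data$grass)) |>
    dplyr::select("plot_id", "grass", "grass_excluded")
}

#' Validate coarse-woody-debris pieces at ingest
#'
#' Pieces must exceed 3 cm diameter at the transect intersection and 0.5 m
#' length; anything smaller is a recording error and is rejected with the
#' offending row numbers.
#'
#' @param cwd CWD table (`diameter_cm`, `length_m`).
#' @return The table, invisibly, if valid.
#' @export
validate_cwd <- function(cwd) {
  bad <- which(cwd$diameter_cm <= 3 | cwd$length_m <= 0.5)
  if (length(bad)) {
    rlang::abort(
      sprintf("CWD pieces below the 3 cm / 0.5 m thresholds at row(s): %s",
              paste(head(bad, 10), collapse = ", ")),
      class = "mopane_validation_error")
  }
  invisible(cwd)
}

#' Per-plot coarse woody debris carbon
#'
#' Line-intersect estimator over the plot's transects: volume per hectare is
#' `(pi^2 / (8 L)) * sum(d_i^2) * 1e4` with piece diameters `d_i` and total
#' transect length `L` in metres, converted to carbon mass with decay-class
#' wood densities and a carbon fraction.
#'
#' @param cwd CWD table (`plot_id`, `diameter_cm`, `decay_class`).
#' @param plots Plot table (supplies the plot list; plots without pieces get
#'   zero).
#' @param constants Decay densities and carbon fraction, see
#'   [default_cwd_constants()].
#' @param transect_length Total transect length per plot in m (four 20 m
#'   transects by default).
#' @return Tibble `plot_id`, `cwd` (Mg C ha^-1).
#' @export
cwd_biomass <- function(cwd, plots, constants = default_cwd_constants(),
                        transect_length = 80) {
  if (transect_length <= 0) {
    rlang::abort("total transect length must be positive", class = "mopane_domain_error")
  }
  validate_cwd(cwd)
  per_plot <- cwd |>
    dplyr::mutate(
      d_m = .data$diameter_cm / 100,
      density = constants$density[as.character(.data$decay_class)],
      piece_c = pi^2 / (8 * transect_length) * .data$d_m^2 * 1e4 *
        .data$density * constants$carbon_fraction
    ) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(cwd = sum(.data$piece_c), .groups = "drop")
  plots |>
    dplyr::select("plot_id") |>
    dplyr::left_join(per_plot, by = "plot_id") |>
    dplyr::mutate(cwd = dplyr::coalesce(.data$cwd, 0))
}

#' All per-plot structural metrics of a dataset
#'
#' Convenience wrapper joining [plot_structure()], [grass_biomass()] and
#' [cwd_biomass()] into one per-plot record (the `plots_structure` table).
#'
#' @param dataset A `study_dataset` (or any list with `stems`, `quadrats`,
#'   `cwd`, `plots`).
#' @param allometry,taper Inventory configuration.
#' @return A tibble with one row per plot and all structural metrics.
#' @export
plot_metrics <- function(dataset, allometry = default_allometry(),
                         taper = default_taper()) {
  plot_structure(dataset$stems, dataset$plots, allometry, taper) |>
    dplyr::left_join(grass_biomass(dataset$quadrats, dataset$plots), by = "plot_id") |>
    dplyr::left_join(cwd_biomass(dataset$cwd, dataset$plots), by = "plot_id")
}

#' Standard error of the mean with small-n suppression
#'
#' Sample SD over the square root of n; reported as `NA` when fewer than
#' `min_n` observations are available (errors could not be estimated for
#' types with n < 4 plots).
#'
#' @param x Numeric vector (`NA`s dropped).
#' @param min_n Minimum n for an SE to be reported.
#' @return SE of the mean, or `NA`.
#' @export
se_mean <- function(x, min_n = 4) {
  x <- x[!is.na(x)]
  if (length(x) < min_n) return(NA_real_)
  sd(x) / sqrt(length(x))
}
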