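#' Current-state analysis of a study dataset
#'
#' Chains the core stages on one dataset: per-plot structure and services,
#' woodland typology (Bray-Curtis / k-means with Calinski-Harabasz
#' selection), grass envelope, class-amalgamated parameters, and
#' area-weighted village service estimates.
#'
#' @param dataset A `study_dataset` (from [gen_dataset()] or
#'   [read_dataset()]).
#' @param k_max,seed Typology settings, see [select_k()].
#' @param quantile Grass-envelope level.
#' @param area_ha Village sample area (ha).
#' @param allometry,taper Inventory configuration.
#' @param fallback When `TRUE` (default), a (class, type) cell with land
#'   cover but no sampled plots takes the class-pooled parameters of that
#'   type instead of raising an error; set `FALSE` to require full coverage.
#' @return A list of class `mopane_analysis`: `metrics`, `typology`,
#'   `types`, `envelope`, `params`, `estimates`, `class_map`, plus the
#'   inputs needed to re-run scenarios.
#' @export
analyse_current <- function(dataset, k_max = 8, seed = 1, quantile = 0.9,
                            area_ha = village_area_ha(),
                            allometry = default_allometry(),
                            taper = default_taper(),
                            fallback = TRUE) {
  validate_dataset(dataset)
  metrics <- plot_metrics(dataset, allometry, taper)
  abund <- relative_abundance(dataset$stems, allometry, taper)
  typology <- select_k(abund, k_max = k_max, seed = seed)
  types <- assign_types(typology, dataset$plots)
  class_map <- if (!is.null(dataset$truth$villages)) {
    dataset$truth$villages[c("village", "class")]
  } else if (!is.null(dataset$villages)) {
    dataset$villages[c("village", "class")]
  } else {
    dplyr::distinct(dataset$plots, .data$village) |> dplyr::mutate(class = "all")
  }
  envelope <- fit_grass_envelope(metrics$stem_density, metrics$grass,
                                 quantile = quantile)
  params <- service_params(dataset$stems, dataset$plots, dataset$links,
                           envelope, types, class_map, allometry, taper,
                           landcover = dataset$landcover, fallback = fallback)
  estimates <- village_totals(params, dataset$landcover, class_map, area_ha)
  structure(list(
    metrics = metrics, typology = typology, types = types,
    envelope = envelope, params = params, estimates = estimates,
    class_map = class_map, area_ha = area_ha,
    allometry = allometry, taper = taper, fallback = fallback
  ), class = "mopane_analysis")
}

# Amalgamated per-(class, type) service parameters from a stem table. With
# `landcover` supplied and `fallback = TRUE`, (class, type) cells that the
# plot sample missed but the land cover requires are filled with the
# class-pooled (study-wide) parameters of that type — the same
# sample-size-driven pooling rationale as class amalgamation itself.
service_params <- function(stems, plots, links, envelope, types, class_map,
                           allometry = default_allometry(),
                           taper = default_taper(),
                           landcover = NULL, fallback = FALSE) {
  values <- plot_services(stems, plots, links, envelope, allometry, taper) |>
    tidyr::pivot_wider(names_from = "service", values_from = "value")
  params <- amalgamate(values, types, class_map) |>
    dplyr::rename(service = "variable")
  if (fallback && !is.null(landcover)) {
    pooled <- amalgamate(values, types,
                         dplyr::mutate(class_map, class = "(all)")) |>
      dplyr::rename(service = "variable") |>
      dplyr::select(-"class")
    required <- landcover |>
      dplyr::filter(.data$fraction > 0) |>
      dplyr::left_join(class_map, by = "village") |>
      dplyr::distinct(.data$class, .data$type) |>
      dplyr::cross_join(dplyr::distinct(params, .data$service))
    gaps <- dplyr::anti_join(required, params,
                             by = c("class", "type", "service"))
    if (nrow(gaps)) {
      fill <- dplyr::inner_join(gaps, pooled, by = c("type", "service"))
      params <- dplyr::bind_rows(params, fill)
    }
  }
  params
}

#' Counterfactual charcoal scenarios for an analysed dataset
#'
#' Applies the stem-level counterfactuals ([apply_no_charcoal()],
#' [apply_total_charcoal()]), recomputes the class-amalgamated parameters
#' and village totals from the modified plots (the typology labels and the
#' grass envelope are held at their current-state fits), and expresses each
#' service as a percent change with a propagated 95% CI.
#'
#' @param dataset The `study_dataset` the analysis was run on.
#' @param analysis The matching [analyse_current()] result.
#' @param method CI method for [scenario_change()].
#' @return A `scenario_results` tibble covering both scenarios.
#' @export
run_scenarios <- function(dataset, analysis, method = c("delta", "mc")) {
  method <- match.arg(method)
  counterfactuals <- list(
    no_charcoal = apply_no_charcoal(dataset$stems, dataset$links, analysis$taper),
    total_charcoal = apply_total_charcoal(dataset$stems, dataset$links, analysis$taper)
  )
  estimates <- purrr::map(counterfactuals, function(stems) {
    params <- service_params(stems, dataset$plots, dataset$links,
                             analysis$envelope, analysis$types,
                             analysis$class_map, analysis$allometry,
                             analysis$taper,
                             landcover = dataset$landcover,
                             fallback = isTRUE(analysis$fallback))
    village_totals(params, dataset$landcover, analysis$class_map,
                   analysis$area_ha)
  })
  out <- purrr::imap(estimates, function(est, name) {
    scenario_change(analysis$estimates, est, scenario = name, method = method)
  }) |>
    purrr::list_rbind()
  class(out) <- c("scenario_results", class(out))
  attr(out, "counterfactual_estimates") <- estimates
  out
}

#' Run the full pipeline
#'
#' Synthesises (or accepts) a study dataset, runs the current-state
#' analysis, both charcoal scenarios, the survey summaries and the
#' trend-concordance report, and optionally writes all output tables plus a
#' JSON run manifest to a directory.
#'
#' @param config A [synth_config()]; ignored when `dataset` is supplied.
#' @param dataset Optional pre-built `study_dataset`.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Seed for the typology restarts.
#' @param ... Passed to [analyse_current()].
#' @return A list of class `mopane_report`: `dataset`, `analysis`,
#'   `scenarios`, `survey`, `concordance`, `plot_counts`, `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), dataset = NULL,
                         out_dir = NULL, seed = config$seed, ...) {
  if (is.null(dataset)) dataset <- gen_dataset(config)
  analysis <- analyse_current(dataset, seed = seed, ...)
  scenarios <- run_scenarios(dataset, analysis)
  survey <- survey_percentages(dataset$survey)
  concordance <- trend_concordance(dataset$trends, scenarios)
  counts <- plot_counts(analysis$types, dataset$plots, analysis$class_map)

  manifest <- list(
    package = "mopane",
    version = as.character(utils::packageVersion("mopane")),
    seed = seed,
    config_hash = rlang::hash(dataset),
    n_plots = nrow(dataset$plots),
    typology_k = analysis$typology$k,
    concordance_rate = attr(concordance, "concordance_rate")
  )
  out <- structure(list(
    dataset = dataset, analysis = analysis, scenarios = scenarios,
    survey = survey, concordance = concordance, plot_counts = counts,
    manifest = manifest
  ), class = "mopane_report")

  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.mopane_report <- function(x, ...) {
  cat("<mopane_report>\n")
  cat(sprintf("  %d plots, typology k = %d, trend concordance %.0f%%\n",
              x$manifest$n_plots, x$manifest$typology_k,
              100 * x$manifest$concordance_rate))
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits the standard CSV outputs (`plots_structure.csv`,
#' `class_type_params.csv`, `services_current.csv`,
#' `services_scenarios.csv`, `survey_percentages.csv`,
#' `trend_concordance.csv`, `typology.json`) and `manifest.json` (package
#' version, seed, config hash, per-file md5 hashes).
#'
#' @param report A `mopane_report`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name))
  }
  w(report$analysis$metrics, "plots_structure.csv")
  w(report$analysis$params, "class_type_params.csv")
  w(dplyr::select(report$analysis$estimates, -"by_type"), "services_current.csv")
  w(report$scenarios, "services_scenarios.csv")
  w(report$survey, "survey_percentages.csv")
  w(report$concordance, "trend_concordance.csv")
  w(report$plot_counts, "plot_counts.csv")
  jsonlite::write_json(
    list(k = report$analysis$typology$k,
         ch_scores = report$analysis$typology$ch_scores,
         labels = as.list(report$analysis$typology$labels)),
    file.path(out_dir, "typology.json"), auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- c(report$manifest,
                list(files = as.list(tools::md5sum(files))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a study dataset's schema
#'
#' Checks that every required table and column is present and that basic
#' invariants hold (positive diameters, fractions in [0,1], CWD thresholds),
#' reporting offending tables, columns and row numbers by name.
#'
#' @param dataset A `study_dataset`-like list.
#' @return Invisibly, the dataset.
#' @export
validate_dataset <- function(dataset) {
  schema <- list(
    plots = c("plot_id", "village", "radius_m", "burnt"),
    stems = c("plot_id", "village", "species", "diameter", "pom", "alive",
              "cut", "stump_height"),
    quadrats = c("plot_id", "fresh_g", "dry_fraction"),
    cwd = c("plot_id", "diameter_cm", "length_m", "decay_class"),
    landcover = c("village", "type", "fraction"),
    links = c("service", "species", "metric", "dbh_min", "dbh_max")
  )
  for (tbl in names(schema)) {
    if (is.null(dataset[[tbl]])) {
      rlang::abort(sprintf("dataset is missing table '%s'", tbl),
                   class = "mopane_validation_error")
    }
    missing <- setdiff(schema[[tbl]], names(dataset[[tbl]]))
    if (length(missing)) {
      rlang::abort(sprintf("table '%s' lacks column(s): %s", tbl,
                           paste(missing, collapse = ", ")),
                   class = "mopane_validation_error")
    }
  }
  bad <- which(dataset$stems$diameter <= 0 | dataset$stems$pom <= 0)
  if (length(bad)) {
    rlang::abort(sprintf("stems: non-positive diameter or pom at row(s): %s",
                         paste(head(bad, 10), collapse = ", ")),
                 class = "mopane_validation_error")
  }
  bad <- which(dataset$landcover$fraction < 0 | dataset$landcover$fraction > 1)
  if (length(bad)) {
    rlang::abort(sprintf("landcover: fraction outside [0,1] at row(s): %s",
                         paste(head(bad, 10), collapse = ", ")),
                 class = "mopane_validation_error")
  }
  validate_cwd(dataset$cwd)
  invisible(dataset)
}
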