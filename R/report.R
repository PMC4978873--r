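#' Household-survey service-use percentages
#'
#' Per-village and pooled percentages of sampled households using each
#' provisioning service, plus the sampling coverage (sampled over total
#' households). Display values are rounded half-up to whole percent;
#' unrounded values are retained.
#'
#' @param survey Long survey table: `village`, `households` (N), `sampled`
#'   (n), `service`, `users`.
#' @return A tibble with per-village rows and one `"(pooled)"` row per
#'   service: `village`, `service`, `users`, `sampled`, `pct`,
#'   `pct_display`, and sampling coverage columns.
#' @export
survey_percentages <- function(survey) {
  validate_survey(survey)
  per_village <- survey |>
    dplyr::mutate(pct = 100 * .data$users / .data$sampled)
  pooled <- survey |>
    dplyr::group_by(.data$service) |>
    dplyr::summarise(users = sum(.data$users),
                     sampled = sum(.data$sampled),
                     households = sum(.data$households),
                     .groups = "drop") |>
    dplyr::mutate(village = "(pooled)",
                  pct = 100 * .data$users / .data$sampled)
  dplyr::bind_rows(per_village, pooled) |>
    dplyr::mutate(pct_display = round_half_up(.data$pct),
                  coverage_pct = 100 * .data$sampled / .data$households,
                  coverage_display = round_half_up(.data$coverage_pct)) |>
    dplyr::select("village", "service", "users", "sampled", "households",
                  "pct", "pct_display", "coverage_pct", "coverage_display")
}

validate_survey <- function(survey) {
  need <- c("village", "households", "sampled", "service", "users")
  missing <- setdiff(need, names(survey))
  if (length(missing)) {
    rlang::abort(sprintf("survey table lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "mopane_validation_error")
  }
  bad <- which(survey$users > survey$sampled | survey$sampled > survey$households |
                 survey$users < 0)
  if (length(bad)) {
    rlang::abort(sprintf("survey counts violate 0 <= users <= sampled <= households at row(s): %s",
                         paste(head(bad, 10), collapse = ", ")),
                 class = "mopane_validation_error")
  }
  invisible(survey)
}

# Half-up rounding to integers, matching how percentages are presented.
round_half_up <- function(x) floor(x + 0.5)

#' Concordance of perceived trends with the "no charcoal" scenario
#'
#' A perceived decline in a service is corroborated when the modelled
#' "no charcoal" gain for that village and service is materially positive
#' (past availability materially higher than current, i.e. a loss has
#' occurred); "no change" is corroborated when the modelled change is not
#' material. Materiality defaults to |percent change| > 10 points and is an
#' interpretive choice.
#'
#' @param trends Tibble `village`, `service`, `trend` with values
#'   `decline` / `no_change` / `not_applicable`.
#' @param scenario_results A `scenario_results` table containing the
#'   `no_charcoal` scenario.
#' @param threshold Material percent-change threshold.
#' @return A tibble `village`, `service`, `trend`, `pct_change`,
#'   `concordant` (`NA` where not applicable), with the summary rate in the
#'   `"concordance_rate"` attribute.
#' @export
trend_concordance <- function(trends, scenario_results, threshold = 10) {
  nc <- scenario_results |>
    dplyr::filter(.data$scenario == "no_charcoal") |>
    dplyr::select("village", "service", "pct_change")
  out <- trends |>
    dplyr::left_join(nc, by = c("village", "service")) |>
    dplyr::mutate(
      material_gain = !is.na(.data$pct_change) & .data$pct_change > threshold,
      concordant = dplyr::case_when(
        .data$trend == "not_applicable" | is.na(.data$pct_change) ~ NA,
        .data$trend == "decline" ~ .data$material_gain,
        .data$trend == "no_change" ~ !.data$material_gain
      )
    ) |>
    dplyr::select("village", "service", "trend", "pct_change", "concordant")
  attr(out, "concordance_rate") <- mean(out$concordant, na.rm = TRUE)
  out
}

extdata_path <- function(file) {
  system.file("extdata", file, package = "mopane", mustWork = TRUE)
}

#' Published Mabalane study tables
#'
#' Accessors for the printed study tables shipped with the package as typed
#' fixtures: the household-survey counts (`mabalane_survey()`), the
#' plot-count bookkeeping by village and woodland type
#' (`mabalane_plot_counts()`) and the perceived temporal trends
#' (`mabalane_trends()`). These are data read from the publication, not
#' outputs of this pipeline.
#'
#' @return A tibble.
#' @export
mabalane_survey <- function() {
  readr::read_csv(extdata_path("mabalane_survey.csv"),
                  show_col_types = FALSE)
}

#' @rdname mabalane_survey
#' @export
mabalane_plot_counts <- function() {
  readr::read_csv(extdata_path("mabalane_plot_counts.csv"),
                  show_col_types = FALSE)
}

#' @rdname mabalane_survey
#' @export
mabalane_trends <- function() {
  readr::read_csv(extdata_path("mabalane_trends.csv"),
                  show_col_types = FALSE)
}
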