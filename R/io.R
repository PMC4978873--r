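#' Write a study dataset to delimited files
#'
#' Emits the generator's external interface: `plots.csv`, `stems.csv`,
#' `quadrats.csv`, `cwd.csv`, `landcover.csv`, `links.csv`, `survey.csv`,
#' `trends.csv` and `truth.json` (generator ground truth, including the
#' distributional assumptions). Writing the same dataset twice yields
#' byte-identical files.
#'
#' @param dataset A `study_dataset`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("plots", "stems", "quadrats", "cwd", "landcover", "links",
              "survey", "trends")
  for (tbl in tables) {
    readr::write_csv(dataset[[tbl]], file.path(dir, paste0(tbl, ".csv")))
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study dataset from delimited files
#'
#' Inverse of [write_dataset()]; validates the schema on load.
#'
#' @param dir Directory containing the dataset files.
#' @return A `study_dataset` list.
#' @export
read_dataset <- function(dir) {
  rd <- function(name, types) {
    readr::read_csv(file.path(dir, paste0(name, ".csv")),
                    show_col_types = FALSE)
  }
  ds <- list(
    plots = rd("plots"), stems = rd("stems"), quadrats = rd("quadrats"),
    cwd = rd("cwd"), landcover = rd("landcover"), links = rd("links"),
    survey = rd("survey"), trends = rd("trends")
  )
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(truth$villages)) truth$villages <- tibble::as_tibble(truth$villages)
    if (!is.null(truth$type_params)) truth$type_params <- tibble::as_tibble(truth$type_params)
    ds$truth <- truth
  }
  class(ds$links) <- c("service_links", class(ds$links))
  ds <- structure(ds, class = "study_dataset")
  validate_dataset(ds)
  ds
}
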