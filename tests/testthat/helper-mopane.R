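# Shared fixture builders; everything is generated in code at test time.

# A small but complete synthetic study: 7 villages x 6 plots.
small_config <- function(seed = 101, plots = 6) {
  synth_config(plots_per_village = plots, seed = seed)
}

# Cache the expensive shared fixtures once per test run.
.fixtures <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- gen_dataset(small_config())
  .fixtures$small
}

# Full-size study (7 x 24 plots) analysed end to end; reused by several files.
full_report <- function() {
  if (is.null(.fixtures$report)) {
    .fixtures$report <- run_pipeline(synth_config(seed = 2024))
  }
  .fixtures$report
}

# Balanced per-type plot set (truth known exactly): n plots drawn from each
# woodland type's parameters, no cutting.
typed_plots <- function(n_per_type = 30, seed = 501) {
  key <- sprintf("typed_%d_%d", n_per_type, seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  params <- woodland_type_params()
  cfg <- synth_config(dead_standing_fraction = 0, pom_offset_fraction = 0)
  stems <- list(); truth <- character(0); plot_ids <- character(0)
  for (ti in seq_len(nrow(params))) {
    for (j in seq_len(n_per_type)) {
      id <- sprintf("T%d-%02d", ti, j)
      p <- gen_plot(as.list(params[ti, ]), cut_fraction = 0,
                    seed = seed + ti * 1000 + j, config = cfg)
      if (nrow(p$stems)) {
        stems[[id]] <- dplyr::mutate(p$stems, plot_id = id, village = "V",
                                     .before = 1)
      }
      truth <- c(truth, params$type[ti]); plot_ids <- c(plot_ids, id)
    }
  }
  out <- list(stems = purrr::list_rbind(stems),
              truth = stats::setNames(truth, plot_ids))
  .fixtures[[key]] <- out
  out
}

# Hand-rolled plot tables for oracle tests.
make_plots <- function(ids, village = "V", radius_m = 20, burnt = FALSE) {
  tibble::tibble(plot_id = ids, village = village, radius_m = radius_m,
                 burnt = burnt)
}

make_stems <- function(plot_id, species, diameter, pom = 1.3, alive = TRUE,
                       cut = FALSE, stump_height = NA_real_, village = "V") {
  tibble::tibble(plot_id = plot_id, village = village, species = species,
                 diameter = diameter, pom = pom, alive = alive, cut = cut,
                 stump_height = stump_height)
}

# A minimal service-link table with known species sets.
toy_links <- function() {
  tibble::tibble(
    service = c(rep("charcoal", 2), rep("firewood", 2), "construction",
                rep("food", 2), "medicine", "grass"),
    species = c("C. mopane", "Combretum spp.",
                "C. mopane", "sp. 01",
                "C. mopane",
                "C. mopane", "sp. 02",
                "sp. 02",
                NA),
    metric = c("biomass", "biomass", "biomass", "biomass", "biomass",
               "stem_density", "stem_density", "stem_density",
               "grass_potential"),
    dbh_min = c(10, 10, 5, 5, 5, 5, 5, 5, NA),
    dbh_max = c(Inf, Inf, 20, 20, 15, Inf, Inf, Inf, NA)
  )
}

# Best label agreement between clusterings under permutation matching
# (exhaustive over permutations; fine for k <= 6).
label_agreement <- function(found, truth) {
  f <- as.character(found); t <- as.character(truth)
  fl <- unique(f); tl <- unique(t)
  if (length(fl) > 7) stop("too many clusters for exhaustive matching")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  pad <- c(tl, rep(NA, max(0, length(fl) - length(tl))))
  best <- 0
  for (p in perms(pad)) {
    map <- stats::setNames(p[seq_along(fl)], fl)
    agree <- mean(!is.na(map[f]) & map[f] == t)
    best <- max(best, agree)
  }
  best
}
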