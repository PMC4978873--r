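#' Per-plot relative biomass abundance matrix
#'
#' Builds the plots-by-species matrix of relative above-ground-biomass shares
#' that the woodland typology is clustered on. Rows sum to 1; plots with no
#' live stems are excluded (they are assigned a type separately).
#'
#' @param stems Stem table.
#' @param allometry,taper Inventory configuration.
#' @return A numeric matrix, rownames plot ids, colnames species.
#' @export
relative_abundance <- function(stems, allometry = default_allometry(),
                               taper = default_taper()) {
  live <- live_intact(stems) |>
    dplyr::mutate(dbh = correct_dbh(.data$diameter, .data$pom, taper),
                  agb_stem = stem_agb(.data$dbh, allometry))
  wide <- live |>
    dplyr::group_by(.data$plot_id, .data$species) |>
    dplyr::summarise(agb = sum(.data$agb_stem), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "agb",
                       values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$plot_id
  m / rowSums(m)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, bounded in [0, 1]; 0 iff the vectors are
#' equal and 1 for disjoint supports. Undefined (error) when both vectors
#' are all zero.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
#' @examples
#' bray_curtis(c(3, 1), c(1, 1))  # 1/3
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("vectors must have equal length", class = "mopane_domain_error")
  }
  if (any(x < 0) || any(y < 0)) {
    rlang::abort("abundances must be non-negative", class = "mopane_domain_error")
  }
  denom <- sum(x + y)
  if (denom == 0) {
    rlang::abort("Bray-Curtis undefined for two all-zero vectors",
                 class = "mopane_domain_error")
  }
  sum(abs(x - y)) / denom
}

#' Calinski-Harabasz index of a partition
#'
#' Between-cluster over within-cluster variance ratio,
#' `CH = (B / (k - 1)) / (W / (n - k))`, with B and W the between- and
#' within-cluster sums of squared Euclidean distances to the relevant
#' centroids.
#'
#' @param x Numeric matrix (rows = observations).
#' @param labels Cluster labels, length `nrow(x)`.
#' @return The CH value.
#' @export
ch_index <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) {
    rlang::abort("CH needs 2 <= k < n", class = "mopane_domain_error")
  }
  grand <- colMeans(x)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    rows <- x[labels == g, , drop = FALSE]
    centre <- colMeans(rows)
    w <- w + sum(sweep(rows, 2, centre)^2)
    b <- b + nrow(rows) * sum((centre - grand)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Select the number of woodland types and cluster the plots
#'
#' Runs k-means (25 restarts per k, seeded) on the Hellinger-transformed
#' relative-abundance rows (square roots of the shares, the standard
#' pre-transformation that makes Euclidean k-means appropriate for
#' compositional vegetation data) for k = 2..`k_max`, scores each partition
#' with the Calinski-Harabasz criterion, and keeps the argmax (ties broken
#' toward smaller k). The Bray-Curtis / average-linkage dendrogram on the
#' raw shares is fitted alongside as the legend for naming and inspection.
#'
#' @param abundance Relative-abundance matrix from [relative_abundance()].
#' @param k_max Largest k to try (must be < number of plots).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Restarts per k.
#' @param transform `"hellinger"` (default) or `"none"` for k-means on the
#'   raw shares.
#' @return A `woodland_typology` object: `k`, `labels` (named by plot),
#'   `ch_scores` tibble, `centers`, `tree` (hclust), `abundance` (raw
#'   shares).
#' @export
select_k <- function(abundance, k_max = 8, seed = 1, nstart = 25,
                     transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  raw <- as.matrix(abundance)
  x <- if (transform == "hellinger") sqrt(raw) else raw
  n <- nrow(x)
  if (k_max >= n) {
    rlang::abort("k_max must be smaller than the number of plots",
                 class = "mopane_domain_error")
  }
  n_distinct_rows <- nrow(unique(as.data.frame(x)))
  if (n_distinct_rows < 2) {
    rlang::abort("degenerate abundance matrix: fewer than two distinct rows",
                 class = "mopane_domain_error")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  fits <- purrr::map(2:min(k_max, n_distinct_rows), function(k) {
    km <- kmeans(x, centers = k, nstart = nstart, iter.max = 100)
    list(k = k, km = km, ch = ch_index(x, km$cluster))
  })
  ch_scores <- tibble::tibble(
    k = purrr::map_int(fits, "k"),
    ch = purrr::map_dbl(fits, "ch")
  )
  best <- fits[[which.max(ch_scores$ch)]]  # which.max takes the first: ties to smaller k

  tree <- hclust(vegan::vegdist(raw, method = "bray"), method = "average")

  structure(list(
    k = best$k,
    labels = setNames(best$km$cluster, rownames(x)),
    centers = best$km$centers,
    ch_scores = ch_scores,
    tree = tree,
    abundance = raw,
    transform = transform
  ), class = "woodland_typology")
}

#' @export
print.woodland_typology <- function(x, ...) {
  cat(sprintf("<woodland_typology> k = %d over %d plots (CH = %.1f)\n",
              x$k, length(x$labels), max(x$ch_scores$ch)))
  invisible(x)
}

default_indicator_species <- function() {
  c("Androstachys forest" = "A. johnsonii",
    "Mopane woodland" = "C. mopane",
    "Combretum woodland" = "Combretum spp.",
    "Boscia woodland" = "B. albitrunca",
    "shrub Mopane" = "Aloe spp.")
}

#' Name clusters by their indicator species
#'
#' Assigns each cluster a woodland-type name by greedy matching on the mean
#' relative-biomass share of each type's indicator species (highest shares
#' assigned first, each type used at most once). Clusters matching no
#' indicator are named after their own dominant species.
#'
#' @param typology A `woodland_typology`.
#' @param indicators Named character vector, type name -> indicator species.
#' @return Tibble `plot_id`, `cluster`, `type`; also a `cluster_names`
#'   attribute (cluster -> type).
#' @export
name_clusters <- function(typology, indicators = default_indicator_species()) {
  x <- typology$abundance
  labels <- typology$labels
  clusters <- sort(unique(labels))
  profile <- t(vapply(clusters, function(g) colMeans(x[labels == g, , drop = FALSE]),
                      numeric(ncol(x))))
  rownames(profile) <- clusters

  present <- indicators[indicators %in% colnames(x)]
  score <- expand.grid(cluster = clusters, type = names(present),
                       stringsAsFactors = FALSE)
  score$share <- mapply(function(cl, ty) profile[as.character(cl), present[[ty]]],
                        score$cluster, score$type)
  score <- score[order(-score$share), ]
  assigned <- character(0)
  for (i in seq_len(nrow(score))) {
    cl <- as.character(score$cluster[i]); ty <- score$type[i]
    if (score$share[i] <= 0) break
    if (!cl %in% names(assigned) && !ty %in% assigned) assigned[cl] <- ty
  }
  for (cl in setdiff(as.character(clusters), names(assigned))) {
    assigned[cl] <- colnames(profile)[which.max(profile[cl, ])]
  }
  out <- tibble::tibble(plot_id = names(labels),
                        cluster = unname(labels),
                        type = unname(assigned[as.character(labels)]))
  attr(out, "cluster_names") <- assigned
  out
}

#' Assign woodland types to every plot
#'
#' Combines clustering labels with the fallback for plots excluded from
#' clustering (no live stems): those take the type of their land-cover
#' stratum when the dataset carries one, else `"other"`.
#'
#' @param typology A `woodland_typology`.
#' @param plots Plot table; an optional `true_type` column (the generator's
#'   stratum) is only used for empty plots, mirroring a field-assigned
#'   land-cover stratum.
#' @param indicators Indicator map for [name_clusters()].
#' @return Tibble `plot_id`, `type`.
#' @export
assign_types <- function(typology, plots,
                         indicators = default_indicator_species()) {
  named <- name_clusters(typology, indicators)
  out <- plots |>
    dplyr::select("plot_id") |>
    dplyr::left_join(dplyr::select(named, "plot_id", "type"), by = "plot_id")
  if ("true_type" %in% names(plots)) {
    strata <- dplyr::select(plots, "plot_id", stratum = "true_type")
    out <- out |>
      dplyr::left_join(strata, by = "plot_id") |>
      dplyr::mutate(type = dplyr::coalesce(.data$type, .data$stratum)) |>
      dplyr::select(-"stratum")
  }
  dplyr::mutate(out, type = dplyr::coalesce(.data$type, "other"))
}

#' Amalgamate per-plot values within chronosequence classes
#'
#' Plot samples are sparse per village, so parameters are pooled within
#' chronosequence classes: for each (class, woodland type) cell the mean,
#' standard error of the mean (suppressed as `NA` when n < 4) and plot count
#' of each value column are computed.
#'
#' @param values Per-plot tibble carrying `plot_id`, a `village` column, and
#'   the value columns to summarise.
#' @param types Tibble `plot_id`, `type` from [assign_types()].
#' @param class_map Tibble `village`, `class`.
#' @param cols Tidy-selection of value columns (default: all numeric columns
#'   other than identifiers).
#' @return A tibble with one row per (class, type, variable): `mean`, `se`,
#'   `n`.
#' @export
amalgamate <- function(values, types, class_map,
                       cols = dplyr::where(is.numeric)) {
  joined <- values |>
    dplyr::left_join(types, by = "plot_id") |>
    dplyr::left_join(class_map, by = "village")
  if (any(is.na(joined$class))) {
    rlang::abort("every plot's village needs a chronosequence class",
                 class = "mopane_validation_error")
  }
  long <- joined |>
    dplyr::select("plot_id", "class", "type", {{ cols }}) |>
    dplyr::select(-dplyr::any_of(c("area_ha", "radius_m"))) |>
    tidyr::pivot_longer(-c("plot_id", "class", "type"),
                        names_to = "variable", values_to = "value")
  long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$class, .data$type, .data$variable) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = se_mean(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Plot-count bookkeeping table
#'
#' Cross-tabulates plots by village and assigned woodland type with class and
#' grand totals — the layout used to judge where class amalgamation is needed
#' and where n < 4 forces SE suppression.
#'
#' @param types Tibble `plot_id`, `type`.
#' @param plots Plot table with `village`.
#' @param class_map Tibble `village`, `class`.
#' @return Tibble `class`, `village`, `type`, `n`.
#' @export
plot_counts <- function(types, plots, class_map) {
  plots |>
    dplyr::left_join(types, by = "plot_id") |>
    dplyr::left_join(class_map, by = "village") |>
    dplyr::count(.data$class, .data$village, .data$type, name = "n")
}
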