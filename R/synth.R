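#' Generate the species-to-service link table
#'
#' Reproduces the structure of the field study's species-use table: 6 charcoal
#' species, 5 firewood species of which exactly 3 are shared with charcoal,
#' 10 construction species, 21 food species and 39 medicine species, with
#' C. mopane (the preferred charcoal tree) a member of every tree-based
#' service. Charcoal/firewood/construction are biomass services, food and
#' medicine are stem-density services, and grass is carried as a
#' grass-potential row with no species. DBH bands come from
#' [default_dbh_bands()].
#'
#' @param seed Integer seed for the sampled (non-core) species.
#' @param pool Character vector of candidate species; needs at least 39
#'   distinct names including "C. mopane".
#' @param bands DBH-band tibble, see [default_dbh_bands()].
#' @return A `service_links` tibble: one row per (service, species) plus one
#'   grass row, with columns `service`, `species`, `metric`, `dbh_min`,
#'   `dbh_max`.
#' @export
#' @examples
#' links <- gen_linkage_table(seed = 1)
#' dplyr::count(links, service)
gen_linkage_table <- function(seed = 1, pool = default_species_pool(),
                              bands = default_dbh_bands()) {
  pool <- unique(pool)
  if (length(pool) < 39 || !"C. mopane" %in% pool) {
    rlang::abort("species pool must contain at least 39 distinct names including 'C. mopane'",
                 class = "mopane_config_error")
  }
  sizes <- c(charcoal = 6, firewood = 5, construction = 10,
             food = 21, medicine = 39)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  draw <- function(candidates, n) sample(candidates, n)
  # Charcoal: C. mopane plus Combretum spp. (the two service-providing
  # dominants) plus sampled minor species.
  charcoal_core <- intersect(c("C. mopane", "Combretum spp."), pool)
  charcoal <- c(charcoal_core,
                draw(setdiff(pool, charcoal_core), sizes["charcoal"] - length(charcoal_core)))
  # Firewood: exactly 3 shared with charcoal (incl. C. mopane), 2 not.
  shared <- c("C. mopane", draw(setdiff(charcoal, "C. mopane"), 2))
  firewood <- c(shared, draw(setdiff(pool, charcoal), 2))
  construction_core <- intersect(c("C. mopane", "A. johnsonii"), pool)
  construction <- c(construction_core,
                    draw(setdiff(pool, construction_core),
                         sizes["construction"] - length(construction_core)))
  food <- c("C. mopane", draw(setdiff(pool, "C. mopane"), sizes["food"] - 1))
  medicine <- c("C. mopane", draw(setdiff(pool, "C. mopane"), sizes["medicine"] - 1))

  sets <- list(charcoal = charcoal, firewood = firewood,
               construction = construction, food = food, medicine = medicine)
  metric_of <- c(charcoal = "biomass", firewood = "biomass",
                 construction = "biomass", food = "stem_density",
                 medicine = "stem_density")
  links <- purrr::imap(sets, function(sp, svc) {
    tibble::tibble(service = svc, species = sp, metric = metric_of[[svc]])
  }) |>
    purrr::list_rbind() |>
    dplyr::left_join(bands, by = "service")
  links <- dplyr::bind_rows(
    links,
    tibble::tibble(service = "grass", species = NA_character_,
                   metric = "grass_potential", dbh_min = NA_real_,
                   dbh_max = NA_real_)
  )
  class(links) <- c("service_links", class(links))
  links
}

service_species <- function(links, svc) {
  links$species[links$service == svc & !is.na(links$species)]
}

service_band <- function(links, svc) {
  row <- links[links$service == svc, c("dbh_min", "dbh_max")]
  c(min = min(row$dbh_min), max = max(row$dbh_max))
}

# Expected value of DBH^p for a lognormal(mu, sigma) left-truncated at m.
trunc_lognormal_moment <- function(p, mu, sigma, m) {
  exp(p * mu + p^2 * sigma^2 / 2) *
    pnorm((mu + p * sigma^2 - log(m)) / sigma) /
    pnorm((mu - log(m)) / sigma)
}

#' Calibrate the diameter distribution to a target biomass density
#'
#' Solves for the lognormal meanlog `mu` such that the expected per-stem
#' biomass of a DBH drawn from lognormal(mu, sigma) truncated at `min_dbh`
#' times the stem density equals the target above-ground biomass under a
#' power allometry. This is what ties the generator's Table-of-types stem
#' densities and AGB together: generated plots recover both in expectation.
#'
#' @param stem_density Stems per hectare.
#' @param agb Target biomass, Mg C per hectare.
#' @param sigma Lognormal sdlog of DBH.
#' @param allometry List with `a`, `b` (see [default_allometry()]).
#' @param min_dbh Lower truncation of live-stem DBH in cm (inventory floor).
#' @return The calibrated meanlog.
#' @export
calibrate_dbh_meanlog <- function(stem_density, agb, sigma,
                                  allometry = default_allometry(),
                                  min_dbh = 5) {
  if (stem_density <= 0) {
    rlang::abort("stem density must be positive to calibrate diameters",
                 class = "mopane_config_error")
  }
  target <- agb / stem_density / allometry$a  # target E[DBH^b | DBH >= min]
  f <- function(mu) trunc_lognormal_moment(allometry$b, mu, sigma, min_dbh) - target
  uniroot(f, interval = c(-5, 10), extendInt = "upX", tol = 1e-10)$root
}

rlnorm_trunc <- function(n, meanlog, sdlog, min) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(max(n, 16), meanlog, sdlog)
    out <- c(out, draw[draw >= min])
  }
  out[seq_len(n)]
}

# Stump diameter at measurement height h implied by a DBH under the linear
# taper d(1.3) = d(h) * (1 - taper*(1.3 - h)); inverse of the correction the
# inventory applies, so reconstruction is exact.
inflate_dbh_to_pom <- function(dbh, pom, taper) {
  dbh / (1 - taper * (1.3 - pom))
}

#' Generate one synthetic inventory plot
#'
#' Draws a 20 m-radius plot from a woodland type's parameters: a Poisson
#' number of live stems about density x area, lognormal DBHs (truncated at
#' the 5 cm inventory floor, meanlog calibrated to the type's biomass), a
#' share `cut_fraction` of charcoal-suitable stems converted to stumps
#' (measurement below 1.3 m, diameter inflated by the taper model so stump
#' reconstruction round-trips), standing dead stems, four grass quadrats and
#' four 20 m coarse-woody-debris transects.
#'
#' @param params One row of [woodland_type_params()] (or a list with the same
#'   fields).
#' @param cut_fraction Probability that a charcoal-suitable stem has been cut.
#' @param seed Integer seed.
#' @param charcoal_species Species whose large stems are charcoal-suitable.
#' @param config A `synth_config` supplying radius, taper, allometry and
#'   nuisance fractions.
#' @return A list with tibbles `stems`, `quadrats`, `cwd` and scalar plot
#'   metadata (`radius_m`, `burnt`).
#' @export
gen_plot <- function(params, cut_fraction, seed = 1,
                     charcoal_species = c("C. mopane", "Combretum spp."),
                     config = synth_config()) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  gen_plot_impl(params, cut_fraction, charcoal_species, config)
}

gen_plot_impl <- function(params, cut_fraction, charcoal_species, config) {
  if (cut_fraction < 0 || cut_fraction > 1) {
    rlang::abort("cut_fraction must lie in [0,1]", class = "mopane_config_error")
  }
  if (params$stem_density < 0) {
    rlang::abort("stem density must be non-negative", class = "mopane_config_error")
  }
  area <- plot_area_ha(config$radius_m)
  pool <- if (is.data.frame(params$species_pool)) params$species_pool else params$species_pool[[1]]
  min_dbh <- 5

  n_live <- rpois(1, params$stem_density * area)
  if (n_live > 0 && params$agb > 0) {
    mu <- calibrate_dbh_meanlog(params$stem_density, params$agb,
                                params$dbh_sigma, config$allometry, min_dbh)
    dbh <- rlnorm_trunc(n_live, mu, params$dbh_sigma, min_dbh)
  } else {
    dbh <- rep(min_dbh, n_live)
  }
  species <- if (n_live > 0) {
    sample(pool$species, n_live, replace = TRUE, prob = pool$weight)
  } else character(0)

  stems <- tibble::tibble(
    species = species, true_dbh = dbh,
    diameter = dbh, pom = 1.3,
    alive = TRUE, cut = FALSE, stump_height = NA_real_
  )

  # Some live stems are measured below breast height; their recorded diameter
  # is the (larger) diameter at that point of measurement.
  if (n_live > 0 && config$pom_offset_fraction > 0) {
    off <- runif(n_live) < config$pom_offset_fraction
    pom_off <- runif(sum(off), 0.6, 1.2)
    stems$pom[off] <- pom_off
    stems$diameter[off] <- inflate_dbh_to_pom(stems$true_dbh[off], pom_off, config$taper)
  }

  # Cut charcoal-suitable stems become stumps measured at the stump.
  suitable <- stems$species %in% charcoal_species & stems$true_dbh >= 10
  cut <- suitable & runif(nrow(stems)) < cut_fraction
  if (any(cut)) {
    stump_h <- runif(sum(cut), 0.2, 0.5)
    stems$alive[cut] <- FALSE
    stems$cut[cut] <- TRUE
    stems$stump_height[cut] <- stump_h
    stems$pom[cut] <- stump_h
    stems$diameter[cut] <- inflate_dbh_to_pom(stems$true_dbh[cut], stump_h, config$taper)
  }

  # Standing dead (uncut) stems: excluded downstream from live density and
  # service availability.
  n_dead <- rpois(1, config$dead_standing_fraction * params$stem_density * area)
  if (n_dead > 0) {
    dead_dbh <- rlnorm_trunc(n_dead,
                             calibrate_dbh_meanlog(max(params$stem_density, 1),
                                                   max(params$agb, 0.1),
                                                   params$dbh_sigma,
                                                   config$allometry, min_dbh),
                             params$dbh_sigma, min_dbh)
    stems <- dplyr::bind_rows(stems, tibble::tibble(
      species = sample(pool$species, n_dead, replace = TRUE, prob = pool$weight),
      true_dbh = dead_dbh, diameter = dead_dbh, pom = 1.3,
      alive = FALSE, cut = FALSE, stump_height = NA_real_
    ))
  }

  quadrats <- gen_quadrats(params$grass)
  cwd <- gen_cwd(params$cwd, pool)
  burnt <- runif(1) < config$burnt_fraction

  list(stems = stems, quadrats = quadrats, cwd = cwd,
       radius_m = config$radius_m, burnt = burnt)
}

# Four 1 m^2 quadrats; plot-level gamma variation about the type mean, with
# quadrat-level lognormal noise. Dry Mg/ha = 0.01 * dry g/m^2.
gen_quadrats <- function(grass_mean, n = 4, plot_cv = 0.5, quad_cv = 0.3) {
  if (grass_mean <= 0) {
    return(tibble::tibble(quadrat = seq_len(n), fresh_g = 0,
                          dry_fraction = runif(n, 0.4, 0.6)))
  }
  shape <- 1 / plot_cv^2
  plot_mean_gm2 <- rgamma(1, shape = shape, scale = grass_mean * 100 / shape)
  sdlog <- sqrt(log(1 + quad_cv^2))
  dry_gm2 <- plot_mean_gm2 * rlnorm(n, -sdlog^2 / 2, sdlog)
  dry_fraction <- runif(n, 0.4, 0.6)
  tibble::tibble(quadrat = seq_len(n),
                 fresh_g = dry_gm2 / dry_fraction,
                 dry_fraction = dry_fraction)
}

# Line-intersect CWD pieces over four 20 m transects (L = 80 m). The piece
# count is Poisson with rate chosen so expected carbon mass equals the type
# mean under the decay-density mix.
gen_cwd <- function(cwd_mean, pool, transect_length = 80,
                    meanlog = log(7), sdlog = 0.45, min_d = 3,
                    decay_probs = c(0.3, 0.4, 0.3),
                    constants = default_cwd_constants()) {
  empty <- tibble::tibble(transect = integer(0), diameter_cm = numeric(0),
                          length_m = numeric(0), decay_class = integer(0),
                          species = character(0))
  if (cwd_mean <= 0) return(empty)
  e_d2_cm2 <- trunc_lognormal_moment(2, meanlog, sdlog, min_d)
  mean_density <- sum(constants$density * decay_probs)
  per_piece <- pi^2 / (8 * transect_length) * (e_d2_cm2 / 1e4) * 1e4 *
    mean_density * constants$carbon_fraction
  n <- rpois(1, cwd_mean / per_piece)
  if (n == 0) return(empty)
  tibble::tibble(
    transect = sample.int(4, n, replace = TRUE),
    diameter_cm = rlnorm_trunc(n, meanlog, sdlog, min_d),
    length_m = runif(n, 0.5, 4),
    decay_class = sample(1:3, n, replace = TRUE, prob = decay_probs),
    species = sample(pool$species, n, replace = TRUE, prob = pool$weight)
  )
}

# Household survey counts: per-class service-use probabilities chosen to
# mirror the study pattern (charcoal widespread except where production never
# started, firewood near-universal, food and medicine uncommon).
survey_use_prob <- function(class, cut_fraction) {
  base <- c(charcoal = 0.6, firewood = 0.97, construction = 0.60,
            grass = 0.35, food = 0.19, medicine = 0.15)
  base["charcoal"] <- switch(class, "post-boom" = 0.88, "boom" = 0.57, "pre-boom" = 0.5)
  if (cut_fraction == 0) base["charcoal"] <- 0
  base
}

gen_survey <- function(villages, mean_households = 45, sample_rate = 0.83) {
  purrr::pmap(villages[c("village", "class", "cut_fraction")],
              function(village, class, cut_fraction) {
    N <- max(rpois(1, mean_households), 10)
    n <- max(rbinom(1, N, sample_rate), 5)
    p <- survey_use_prob(class, cut_fraction)
    counts <- setNames(rbinom(length(p), n, p), names(p))
    tibble::tibble(village = village, households = N, sampled = n,
                   service = names(counts), users = as.integer(counts))
  }) |> purrr::list_rbind()
}

# Perceived temporal trends, deterministic from the cut fraction: villages
# that have lost much of the charcoal resource perceive declines in the
# woody services; a village that never produced charcoal reports n.a.
gen_trends <- function(villages) {
  tidyr::expand_grid(village = villages$village, service = services()) |>
    dplyr::left_join(villages[c("village", "class", "cut_fraction")], by = "village") |>
    dplyr::mutate(
      trend = dplyr::case_when(
        service == "charcoal" & .data$cut_fraction == 0 ~ "not_applicable",
        service == "charcoal" & .data$cut_fraction >= 0.2 ~ "decline",
        service == "firewood" & .data$cut_fraction >= 0.35 ~ "decline",
        service == "construction" & .data$cut_fraction >= 0.15 ~ "decline",
        TRUE ~ "no_change"
      )
    ) |>
    dplyr::select("village", "service", "trend")
}

#' Generate a complete synthetic study dataset
#'
#' Runs the generator for every plot of every village in the configuration
#' and assembles the full set of study tables: stems, grass quadrats, coarse
#' woody debris, land cover, service links, household survey counts,
#' perceived trends, and the generator ground truth. Deterministic: the same
#' configuration (including seed) always yields an identical dataset.
#'
#' @param config A [synth_config()].
#' @return A list of class `study_dataset` with tibbles `plots`, `stems`,
#'   `quadrats`, `cwd`, `landcover`, `links`, `survey`, `trends` and a
#'   `truth` list (true type labels per plot live in `plots$true_type`).
#' @export
#' @examples
#' ds <- gen_dataset(synth_config(plots_per_village = 4, seed = 42))
#' nrow(ds$plots)
gen_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  links <- gen_linkage_table(seed = config$seed)
  charcoal_sp <- service_species(links, "charcoal")
  type_params <- config$type_params
  frac_cols <- intersect(names(config$villages), type_params$type)

  plots <- list(); stems <- list(); quadrats <- list(); cwd <- list()
  for (vi in seq_len(nrow(config$villages))) {
    vrow <- config$villages[vi, ]
    fracs <- as.numeric(vrow[1, frac_cols])
    if (sum(fracs) <= 0) {
      rlang::abort(sprintf("village %s has no woodland cover", vrow$village),
                   class = "mopane_config_error")
    }
    for (pi in seq_len(config$plots_per_village)) {
      plot_id <- sprintf("%s-%02d", vrow$village, pi)
      type <- sample(frac_cols, 1, prob = fracs)
      prow <- type_params[type_params$type == type, ]
      p <- gen_plot_impl(as.list(prow), vrow$cut_fraction, charcoal_sp, config)
      plots[[plot_id]] <- tibble::tibble(
        plot_id = plot_id, village = vrow$village, radius_m = p$radius_m,
        burnt = p$burnt, true_type = type
      )
      if (nrow(p$stems)) stems[[plot_id]] <- dplyr::mutate(
        p$stems, plot_id = plot_id, village = vrow$village, .before = 1)
      quadrats[[plot_id]] <- dplyr::mutate(
        p$quadrats, plot_id = plot_id, village = vrow$village, .before = 1)
      if (nrow(p$cwd)) cwd[[plot_id]] <- dplyr::mutate(
        p$cwd, plot_id = plot_id, village = vrow$village, .before = 1)
    }
  }

  landcover <- config$villages |>
    dplyr::select("village", dplyr::all_of(frac_cols)) |>
    tidyr::pivot_longer(-"village", names_to = "type", values_to = "fraction")

  survey <- gen_survey(config$villages)
  trends <- gen_trends(config$villages)

  ds <- structure(list(
    plots = purrr::list_rbind(plots),
    stems = purrr::list_rbind(stems),
    quadrats = purrr::list_rbind(quadrats),
    cwd = purrr::list_rbind(cwd),
    landcover = landcover,
    links = links,
    survey = survey,
    trends = trends,
    truth = list(
      seed = config$seed,
      type_params = dplyr::select(type_params, -"species_pool"),
      villages = config$villages,
      taper = config$taper,
      allometry = config$allometry,
      dbh_distribution = "lognormal per type, meanlog calibrated to type AGB, truncated at 5 cm"
    )
  ), class = "study_dataset")
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat(sprintf("  %d plots in %d villages; %d stems, %d quadrats, %d CWD pieces\n",
              nrow(x$plots), dplyr::n_distinct(x$plots$village),
              nrow(x$stems), nrow(x$quadrats), nrow(x$cwd)))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
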