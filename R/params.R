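#' Default woodland-type parameters
#'
#' Structural parameters of the five Mabalane woodland types used by the
#' synthetic-data generator: mean stem density (stems ha^-1), above-ground
#' woody biomass (Mg C ha^-1), dry grass biomass (Mg ha^-1), coarse woody
#' debris (Mg C ha^-1), the indicator species of each type, and the shape
#' (`dbh_sigma`, the lognormal sdlog) of the stem diameter distribution.
#' The per-type lognormal meanlog is not stored here: it is calibrated at
#' generation time so that expected per-stem biomass times density matches
#' `agb` under the configured allometry (see [calibrate_dbh_meanlog()]).
#'
#' @return A tibble with one row per woodland type and a `species_pool`
#'   list-column of `(species, weight)` tibbles whose weights sum to 1.
#' @export
#' @examples
#' woodland_type_params()
woodland_type_params <- function() {
  pools <- default_species_pools()
  out <- tibble::tibble(
    type = names(pools),
    indicator = c("A. johnsonii", "C. mopane", "Combretum spp.",
                  "B. albitrunca", "Aloe spp."),
    stem_density = c(1764, 769, 639, 582, 103),
    agb          = c(31.7, 11.8, 12.8, 5.4, 7.31),
    grass        = c(0.06, 0.66, 1.06, 0.79, 0.34),
    cwd          = c(3.57, 0.90, 0.98, 0.72, 0.02),
    dbh_sigma    = c(0.45, 0.45, 0.45, 0.40, 0.35),
    species_pool = unname(pools)
  )
  validate_type_params(out)
  out
}

validate_type_params <- function(params) {
  stopifnot(is.data.frame(params))
  if (any(params$stem_density < 0) || any(params$agb < 0) ||
      any(params$grass < 0) || any(params$cwd < 0)) {
    rlang::abort("woodland type means must be non-negative", class = "mopane_config_error")
  }
  if (any(params$dbh_sigma <= 0)) {
    rlang::abort("dbh_sigma must be > 0", class = "mopane_config_error")
  }
  for (pool in params$species_pool) {
    if (abs(sum(pool$weight) - 1) > 1e-8) {
      rlang::abort("species pool weights must sum to 1", class = "mopane_config_error")
    }
  }
  invisible(params)
}

# Synthetic local species names. The five indicator names are kept verbatim
# (they drive typology naming and the service-link logic); everything else is
# an invented local name.
synthetic_species_names <- function(n = 45) {
  sprintf("sp. %02d", seq_len(n))
}

default_species_pools <- function() {
  sp <- synthetic_species_names()
  pool <- function(species, weight) tibble::tibble(species = species, weight = weight)
  list(
    "Androstachys forest" = pool(
      c("A. johnsonii", sp[1:5]),
      c(0.85, 0.05, 0.04, 0.03, 0.02, 0.01)),
    "Mopane woodland" = pool(
      c("C. mopane", sp[6:9], "Combretum spp."),
      c(0.85, 0.04, 0.03, 0.03, 0.03, 0.02)),
    "Combretum woodland" = pool(
      c("Combretum spp.", sp[10:11], "C. mopane", sp[12:15]),
      c(0.78, 0.05, 0.04, 0.03, 0.03, 0.03, 0.02, 0.02)),
    "Boscia woodland" = pool(
      c("B. albitrunca", sp[16:20]),
      c(0.80, 0.06, 0.05, 0.04, 0.03, 0.02)),
    "shrub Mopane" = pool(
      c("Aloe spp.", "C. mopane"),
      c(0.65, 0.35))
  )
}

#' Master species pool for the service-link generator
#'
#' All local names known to the generator: the five verbatim indicator names
#' plus the synthetic local names. At least 39 distinct names are required to
#' populate the medicinal-plant list.
#'
#' @return Character vector of species names; `"C. mopane"` is always first.
#' @export
default_species_pool <- function() {
  c("C. mopane", "A. johnsonii", "Combretum spp.", "B. albitrunca",
    "Aloe spp.", synthetic_species_names())
}

#' Default stem allometry
#'
#' Power-law allometry for per-stem above-ground biomass,
#' AGB (Mg C) = a * DBH^b with DBH in cm. The default coefficients follow
#' the Ryan et al. miombo allometry commonly applied in these woodlands;
#' they are configuration data, not package-validated constants, and should
#' be replaced when site-specific coefficients are available.
#'
#' @return A list with elements `a`, `b`, `form` and `source`.
#' @export
default_allometry <- function() {
  list(a = 2.67e-5, b = 2.58, form = "power",
       source = "Ryan et al. miombo stem allometry (config default)")
}

#' Default diameter bands for tree services
#'
#' The species-use interviews give species, not sizes; these DBH bands are
#' loud configuration defaults: charcoal needs large stems (>= 10 cm),
#' firewood mid-sized stems (5-20 cm), construction poles (5-15 cm), and
#' food/medicine any countable stem (>= 5 cm).
#'
#' @return A tibble with columns `service`, `dbh_min`, `dbh_max` (cm).
#' @export
default_dbh_bands <- function() {
  tibble::tibble(
    service = c("charcoal", "firewood", "construction", "food", "medicine"),
    dbh_min = c(10, 5, 5, 5, 5),
    dbh_max = c(Inf, 20, 15, Inf, Inf)
  )
}

#' Default wood density by decay class and carbon fraction
#'
#' Coarse-woody-debris volume is converted to carbon mass with a decay-class
#' wood density table (Mg m^-3) and a carbon fraction (default 0.47).
#'
#' @return A list with `density` (named numeric, decay classes "1"-"3") and
#'   `carbon_fraction`.
#' @export
default_cwd_constants <- function() {
  list(density = c("1" = 0.58, "2" = 0.45, "3" = 0.30),
       carbon_fraction = 0.47)
}

#' Default per-metre taper rate
#'
#' Linear taper used both to correct diameters measured off 1.3 m to DBH and
#' to reconstruct DBH from stump measurements:
#' d(1.3) = d(pom) * (1 - taper * (1.3 - pom)).
#' @return Numeric scalar (per metre).
#' @export
default_taper <- function() 0.02

#' Village sample-area in hectares
#'
#' Each village landscape is sampled within a 5 km radius of the village
#' centre: pi * 5^2 = 78.54 km^2 = 7854 ha.
#' @param radius_km Sample radius in km (default 5).
#' @return Area in hectares.
#' @export
village_area_ha <- function(radius_km = 5) {
  pi * radius_km^2 * 100
}

services <- function() {
  c("charcoal", "firewood", "construction", "food", "medicine", "grass")
}

tree_services <- function() setdiff(services(), "grass")

#' Default village chronosequence and land-cover composition
#'
#' Seven villages (A-G) in three charcoal-production stages: post-boom
#' (A-C, past their production peak), boom (D-E, producing at peak) and
#' pre-boom (F small-scale only, G none). `cut_fraction` is the share of
#' charcoal-suitable stems already removed, rising along the chronosequence.
#' Land-cover fractions (share of the village sample area per woodland type;
#' the residual is non-woodland "other") mirror the study landscape pattern:
#' village A is Boscia/shrub-heavy, B-C Mopane-heavy, D-G Combretum-heavy
#' with Androstachys forest only in the north.
#'
#' @return A tibble: village, class, cut_fraction, and one fraction column
#'   per woodland type.
#' @export
default_villages <- function() {
  tibble::tribble(
    ~village, ~class,      ~cut_fraction,
    "A", "post-boom", 0.35,
    "B", "post-boom", 0.35,
    "C", "post-boom", 0.35,
    "D", "boom",      0.15,
    "E", "boom",      0.15,
    "F", "pre-boom",  0.05,
    "G", "pre-boom",  0.00
  ) |>
    dplyr::mutate(
      `Androstachys forest` = c(0, 0, 0, 0.10, 0.08, 0.10, 0.10),
      `Mopane woodland`     = c(0.25, 0.45, 0.40, 0.20, 0.20, 0.25, 0.15),
      `Combretum woodland`  = c(0.15, 0.25, 0.30, 0.40, 0.45, 0.40, 0.45),
      `Boscia woodland`     = c(0.25, 0.05, 0.05, 0, 0, 0, 0),
      `shrub Mopane`        = c(0.15, 0, 0.02, 0, 0, 0, 0)
    )
}

#' Build a synthetic-study configuration
#'
#' Bundles everything [gen_dataset()] needs: the village chronosequence with
#' land-cover composition and cut fractions, the woodland-type parameters,
#' plots per village, plot radius, and the seed.
#'
#' @param villages Tibble as returned by [default_villages()].
#' @param type_params Tibble as returned by [woodland_type_params()].
#' @param plots_per_village Number of 20 m-radius plots per village.
#' @param radius_m Plot radius in metres.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration including this seed.
#' @param pom_offset_fraction Fraction of live stems measured below 1.3 m
#'   (their recorded diameter is taken at a lower point of measurement and
#'   must be taper-corrected by the inventory).
#' @param dead_standing_fraction Expected standing dead (uncut) stems as a
#'   fraction of live stem count.
#' @param burnt_fraction Probability a plot is flagged recently burnt
#'   (excluded from grass analysis).
#' @param taper,allometry Taper rate and allometry shared with the inventory.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(villages = default_villages(),
                         type_params = woodland_type_params(),
                         plots_per_village = 24,
                         radius_m = 20,
                         seed = 1,
                         pom_offset_fraction = 0.1,
                         dead_standing_fraction = 0.03,
                         burnt_fraction = 0,
                         taper = default_taper(),
                         allometry = default_allometry()) {
  validate_type_params(type_params)
  frac_cols <- intersect(names(villages), type_params$type)
  if (length(frac_cols) == 0) {
    rlang::abort("villages table has no land-cover fraction columns matching type names",
                 class = "mopane_config_error")
  }
  fr <- as.matrix(villages[frac_cols])
  if (any(fr < 0) || any(fr > 1) || any(rowSums(fr) > 1 + 1e-8)) {
    rlang::abort("land-cover fractions must lie in [0,1] and sum to at most 1 per village",
                 class = "mopane_config_error")
  }
  if (any(villages$cut_fraction < 0) || any(villages$cut_fraction > 1)) {
    rlang::abort("cut fractions must lie in [0,1]", class = "mopane_config_error")
  }
  structure(
    list(villages = villages, type_params = type_params,
         plots_per_village = plots_per_village, radius_m = radius_m,
         seed = as.integer(seed),
         pom_offset_fraction = pom_offset_fraction,
         dead_standing_fraction = dead_standing_fraction,
         burnt_fraction = burnt_fraction,
         taper = taper, allometry = allometry),
    class = "synth_config"
  )
}

plot_area_ha <- function(radius_m) pi * radius_m^2 / 1e4
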