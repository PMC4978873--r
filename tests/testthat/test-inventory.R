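test_that("DBH correction is the identity at 1.3 m and matches the taper formula", {
  expect_equal(correct_dbh(10, 1.3, 0.02), 10)
  expect_equal(correct_dbh(10, 0.3, 0.02), 9.8)
  # monotone in diameter at fixed pom
  d <- sort(runif(20, 5, 50))
  expect_true(all(diff(correct_dbh(d, 0.7, 0.02)) > 0))
  expect_error(correct_dbh(-1, 1.3), class = "mopane_domain_error")
  expect_error(correct_dbh(10, 0), class = "mopane_domain_error")
})

test_that("stem allometry is the configured power law", {
  expect_equal(stem_agb(7, list(a = 1, b = 1, form = "power")), 7)
  expect_equal(stem_agb(10, list(a = 0.03, b = 2.5, form = "power")),
               0.03 * 10^2.5, tolerance = 1e-12)
  expect_equal(stem_agb(10, list(a = 0.03, b = 2.5, form = "power")),
               9.4868, tolerance = 1e-4)
  # doubling DBH multiplies AGB by 2^b
  co <- list(a = 0.01, b = 2.5, form = "power")
  expect_equal(stem_agb(14, co) / stem_agb(7, co), 2^2.5)
  expect_error(stem_agb(0), class = "mopane_domain_error")
  expect_error(stem_agb(10, list(a = 1, b = 1, form = "mystery")),
               class = "mopane_domain_error")
})

test_that("plot structure matches hand-computed values on small plots", {
  plots <- make_plots("p1")
  # empty plot
  empty <- plot_structure(make_stems(character(0), character(0), numeric(0)),
                          plots)
  expect_equal(empty$stem_density, 0)
  expect_equal(empty$agb, 0)
  expect_equal(empty$richness, 0)

  # 100 live stems in a 20 m plot -> 795.77 stems/ha
  stems <- make_stems(rep("p1", 100), rep("C. mopane", 100), rep(10, 100))
  ps <- plot_structure(stems, plots)
  expect_equal(ps$stem_density, 100 * 1e4 / (pi * 400), tolerance = 1e-10)
  expect_equal(ps$stem_density, 795.8, tolerance = 1e-4)

  # 4 species with equal AGB shares -> evenness 1
  stems4 <- make_stems(rep("p1", 4), paste0("s", 1:4), rep(12, 4))
  expect_equal(plot_structure(stems4, plots)$evenness, 1)
  expect_equal(plot_structure(stems4, plots)$richness, 4)
})

test_that("plot structure equals brute-force per-stem summation", {
  set.seed(42)
  allom <- default_allometry()
  for (rep in 1:5) {
    n <- sample(1:10, 1)
    stems <- make_stems(rep("p1", n),
                        sample(c("a", "b", "c"), n, replace = TRUE),
                        runif(n, 5, 40), pom = runif(n, 0.6, 1.3))
    ps <- plot_structure(stems, make_plots("p1"))
    # brute force, one stem at a time
    area <- pi * 20^2 / 1e4
    agb <- 0
    for (i in seq_len(n)) {
      dbh_i <- stems$diameter[i] * (1 - 0.02 * (1.3 - stems$pom[i]))
      agb <- agb + allom$a * dbh_i^allom$b
    }
    expect_equal(ps$agb, agb / area, tolerance = 1e-12)
    expect_equal(ps$stem_density, n / area, tolerance = 1e-12)
    expect_equal(ps$richness, length(unique(stems$species)))
  }
})

test_that("dead and cut stems are excluded from live structure", {
  stems <- dplyr::bind_rows(
    make_stems("p1", "a", 20),
    make_stems("p1", "b", 30, alive = FALSE, cut = TRUE, stump_height = 0.3, pom = 0.3),
    make_stems("p1", "c", 25, alive = FALSE)  # standing dead
  )
  ps <- plot_structure(stems, make_plots("p1"))
  expect_equal(ps$n_live, 1L)
  expect_equal(ps$n_cut, 1L)
  expect_equal(ps$richness, 1L)
})

test_that("grass biomass converts quadrat masses and excludes burnt plots", {
  plots <- make_plots(c("p1", "p2"), burnt = c(FALSE, TRUE))
  quads <- tibble::tibble(plot_id = rep(c("p1", "p2"), each = 4),
                          quadrat = rep(1:4, 2),
                          fresh_g = 100, dry_fraction = 0.5)
  g <- grass_biomass(quads, plots)
  expect_equal(g$grass[g$plot_id == "p1"], 0.5)  # 50 g/m2 -> 0.5 Mg/ha
  expect_true(is.na(g$grass[g$plot_id == "p2"]))
  expect_true(g$grass_excluded[g$plot_id == "p2"])

  zero <- grass_biomass(dplyr::mutate(quads[1:4, ], fresh_g = 0), plots[1, ])
  expect_equal(zero$grass, 0)
  expect_error(grass_biomass(dplyr::mutate(quads, fresh_g = -1), plots),
               class = "mopane_domain_error")
})

test_that("coarse woody debris follows the line-intersect formula", {
  plots <- make_plots("p1")
  none <- cwd_biomass(tibble::tibble(plot_id = character(0),
                                     diameter_cm = numeric(0),
                                     length_m = numeric(0),
                                     decay_class = integer(0)), plots)
  expect_equal(none$cwd, 0)

  one <- tibble::tibble(plot_id = "p1", diameter_cm = 10, length_m = 2,
                        decay_class = 1L)
  consts <- list(density = c("1" = 0.9), carbon_fraction = 0.47)
  got <- cwd_biomass(one, plots, constants = consts, transect_length = 80)
  vol <- pi^2 / (8 * 80) * 0.1^2 * 1e4
  expect_equal(vol, 1.5421, tolerance = 1e-4)
  expect_equal(got$cwd, vol * 0.9 * 0.47, tolerance = 1e-10)
  expect_equal(got$cwd, 0.652, tolerance = 1e-3)

  # doubling every diameter quadruples the volume (and mass)
  two <- dplyr::mutate(one, diameter_cm = 20)
  expect_equal(cwd_biomass(two, plots, constants = consts)$cwd, 4 * got$cwd)

  # undersized pieces are rejected at ingest with row numbers
  bad <- tibble::tibble(plot_id = "p1", diameter_cm = 2, length_m = 2,
                        decay_class = 1L)
  expect_error(cwd_biomass(bad, plots), class = "mopane_validation_error")
  short <- tibble::tibble(plot_id = "p1", diameter_cm = 10, length_m = 0.2,
                          decay_class = 1L)
  expect_error(cwd_biomass(short, plots), class = "mopane_validation_error")
})

test_that("metrics are additive over disjoint stem subsets", {
  set.seed(7)
  stems <- make_stems(rep("p1", 12), sample(letters[1:4], 12, replace = TRUE),
                      runif(12, 6, 30))
  all_ps <- plot_structure(stems, make_plots("p1"))
  a <- plot_structure(stems[1:5, ], make_plots("p1"))
  b <- plot_structure(stems[6:12, ], make_plots("p1"))
  expect_equal(all_ps$agb, a$agb + b$agb, tolerance = 1e-12)
  expect_equal(all_ps$stem_density, a$stem_density + b$stem_density,
               tolerance = 1e-12)
})

test_that("stump reconstruction inverts the taper model", {
  expect_equal(reconstruct_stump_dbh(15, 1.3), 15)
  expect_equal(reconstruct_stump_dbh(12, 0.3, 0.02), 11.76)
  # missing measurement height: NA with a warning, not an error
  expect_warning(out <- reconstruct_stump_dbh(c(12, 10), c(0.3, NA)),
                 "skipped")
  expect_equal(out[1], 11.76)
  expect_true(is.na(out[2]))
  # generator round trip: a 20 cm DBH tree cut at 0.4 m reconstructs to 20 cm
  stump_d <- 20 / (1 - 0.02 * (1.3 - 0.4))
  expect_equal(reconstruct_stump_dbh(stump_d, 0.4, 0.02), 20, tolerance = 1e-12)
})

test_that("SE of a mean matches sd/sqrt(n) and is suppressed below n = 4", {
  x <- c(2, 4, 6, 8)
  expect_equal(se_mean(x), sd(x) / 2)
  expect_equal(se_mean(x), sqrt(sum((x - 5)^2) / 3) / sqrt(4))  # hand SD
  expect_true(is.na(se_mean(c(2, 4))))
  expect_equal(se_mean(rep(3, 5)), 0)
})
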