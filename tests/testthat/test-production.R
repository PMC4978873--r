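test_that("plot-level service availability matches hand summation", {
  plots <- make_plots("p1")
  links <- toy_links()

  # no linked species present
  none <- plot_service(make_stems("p1", "unlinked sp.", 20), plots, links,
                       "charcoal")
  expect_equal(none$value, 0)

  # only cut charcoal stems: no standing service
  cut_only <- make_stems("p1", "C. mopane", 18, pom = 0.3, alive = FALSE,
                         cut = TRUE, stump_height = 0.3)
  expect_equal(plot_service(cut_only, plots, links, "charcoal")$value, 0)

  # three linked stems with AGB 0.1, 0.2, 0.3 Mg C -> 0.6 / area
  a <- default_allometry()
  dbh <- (c(0.1, 0.2, 0.3) / a$a)^(1 / a$b)  # invert allometry; all >= 10 cm
  stems <- make_stems(rep("p1", 3), rep("C. mopane", 3), dbh)
  got <- plot_service(stems, plots, links, "charcoal")
  expect_equal(got$value, 0.6 / (pi * 400 / 1e4), tolerance = 1e-10)
  expect_equal(got$value, 4.775, tolerance = 1e-3)

  expect_error(plot_service(stems, plots, links, "rubber"),
               class = "mopane_domain_error")
})

test_that("DBH bands and metrics drive the production functions", {
  plots <- make_plots("p1")
  links <- toy_links()
  stems <- make_stems(rep("p1", 3), rep("C. mopane", 3), c(8, 15, 30))
  area <- pi * 400 / 1e4

  # charcoal counts only stems >= 10 cm
  charcoal <- plot_service(stems, plots, links, "charcoal")$value
  expect_equal(charcoal, sum(stem_agb(c(15, 30))) / area, tolerance = 1e-12)

  # firewood band is 5-20 cm
  firewood <- plot_service(stems, plots, links, "firewood")$value
  expect_equal(firewood, sum(stem_agb(c(8, 15))) / area, tolerance = 1e-12)

  # food is a stem count, not biomass
  food <- plot_service(stems, plots, links, "food")$value
  expect_equal(food, 3 / area, tolerance = 1e-12)

  # adding a non-linked stem changes no tree-service value
  stems2 <- dplyr::bind_rows(stems, make_stems("p1", "unlinked sp.", 25))
  for (svc in c("charcoal", "firewood", "construction", "food", "medicine")) {
    expect_equal(plot_service(stems2, plots, links, svc)$value,
                 plot_service(stems, plots, links, svc)$value)
  }
})

test_that("grass envelope reproduces a flat ceiling and recovers a known slope", {
  set.seed(91)
  # flat case: constant grass across densities
  d <- runif(40, 100, 2000)
  flat <- fit_grass_envelope(d, rep(1.2, 40), quantile = 0.9)
  expect_equal(as.numeric(predict(flat, c(200, 1500))), c(1.2, 1.2),
               tolerance = 1e-6)

  # decreasing linear envelope: grass = (2.0 - 8e-4 * d) * u^(1/9), u ~ U(0,1)
  # so the 0.9-quantile of grass | d is 0.9^(1/9) ~ 0.988 of the envelope
  n <- 150
  d <- runif(n, 100, 2000)
  env <- 2.0 - 8e-4 * d
  grass <- env * runif(n)^(1 / 9)
  fit <- fit_grass_envelope(d, grass, quantile = 0.9)
  expect_lt(abs(fit$coef[2] - (-8e-4)) / 8e-4, 0.2)

  # predictions clamp at zero and at the fitted range boundary
  p <- predict(fit, c(0, 5000))
  expect_true(all(attr(p, "extrapolated")))
  expect_equal(as.numeric(p), as.numeric(predict(fit, fit$range)),
               tolerance = 1e-12)
  expect_true(all(p >= 0))
})

test_that("grass envelope guards its preconditions", {
  expect_error(fit_grass_envelope(1:5, rep(1, 5)), class = "mopane_domain_error")
  expect_warning(z <- fit_grass_envelope(seq(100, 1000, length.out = 12),
                                         rep(0, 12)),
                 "zero envelope")
  expect_equal(as.numeric(predict(z, 500)), 0)
})

test_that("village totals match hand-propagated errors", {
  class_map <- tibble::tibble(village = "A", class = "c1")

  # single type, fraction 1, mean 2 +/- 0.5 over 7854 ha
  params <- tibble::tibble(class = "c1", type = "T1", service = "charcoal",
                           mean = 2, se = 0.5, n = 10L)
  cover <- tibble::tibble(village = "A", type = "T1", fraction = 1)
  est <- village_totals(params, cover, class_map, area_ha = 7854)
  expect_equal(est$value, 15708)
  expect_equal(est$se, 3927)
  expect_equal(est$ci_lo, 15708 - 1.96 * 3927)

  # two types over 100 and 200 ha of a 300 ha landscape
  params2 <- tibble::tibble(class = "c1", type = c("T1", "T2"),
                            service = "charcoal",
                            mean = c(2, 1), se = c(0.5, 0.2), n = 10L)
  cover2 <- tibble::tibble(village = "A", type = c("T1", "T2"),
                           fraction = c(100 / 300, 200 / 300))
  est2 <- village_totals(params2, cover2, class_map, area_ha = 300)
  expect_equal(est2$value, 400)
  expect_equal(est2$se, sqrt(50^2 + 40^2))
  expect_equal(est2$se, 64.03, tolerance = 1e-3)
  # per-type contributions sum to the total
  expect_equal(sum(est2$by_type[[1]]$contribution), est2$value)

  # all fractions zero: explicit 0 +/- 0
  cover0 <- tibble::tibble(village = "A", type = "T1", fraction = 0)
  est0 <- village_totals(params, cover0, class_map, area_ha = 7854)
  expect_equal(est0$value, 0)
  expect_equal(est0$se, 0)

  # missing parameter for a covered type is a hard, named error
  cover_gap <- tibble::tibble(village = "A", type = "T9", fraction = 0.5)
  expect_error(village_totals(params, cover_gap, class_map),
               class = "mopane_validation_error")
})

test_that("landscape totals are monotone in any per-type mean", {
  class_map <- tibble::tibble(village = "A", class = "c1")
  cover <- tibble::tibble(village = "A", type = c("T1", "T2"),
                          fraction = c(0.3, 0.4))
  base <- tibble::tibble(class = "c1", type = c("T1", "T2"),
                         service = "firewood", mean = c(2, 3),
                         se = c(0.1, 0.1), n = 10L)
  bumped <- dplyr::mutate(base, mean = mean + c(0, 0.5))
  v0 <- village_totals(base, cover, class_map)$value
  v1 <- village_totals(bumped, cover, class_map)$value
  expect_gt(v1, v0)
})

test_that("propagated landscape SE matches the Monte-Carlo oracle within 5%", {
  class_map <- tibble::tibble(village = "A", class = "c1")
  params <- tibble::tibble(class = "c1", type = c("T1", "T2", "T3"),
                           service = "charcoal",
                           mean = c(2, 1, 4), se = c(0.5, 0.2, 0.8), n = 10L)
  cover <- tibble::tibble(village = "A", type = c("T1", "T2", "T3"),
                          fraction = c(0.2, 0.3, 0.1))
  est <- village_totals(params, cover, class_map)
  mc <- village_total_se_mc(params, cover, class_map, "A", "charcoal",
                            n_draws = 1e5, seed = 9)
  expect_lt(abs(est$se - mc) / mc, 0.05)
})

test_that("village sample-area geometry is the 5 km circle", {
  expect_equal(village_area_ha() / 100, 78.53982, tolerance = 1e-6)  # km^2
  expect_equal(village_area_ha(), 7854, tolerance = 1e-4)
})
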