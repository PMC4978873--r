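test_that("the no-charcoal counterfactual restores exactly the charcoal stumps", {
  links <- toy_links()
  stems <- dplyr::bind_rows(
    make_stems("p1", "C. mopane", 20),                       # live charcoal
    make_stems("p1", "C. mopane", 18 / (1 - 0.02), pom = 0.3, # charcoal stump
               alive = FALSE, cut = TRUE, stump_height = 0.3),
    make_stems("p1", "sp. 02", 9 / (1 - 0.02), pom = 0.3,     # non-charcoal stump
               alive = FALSE, cut = TRUE, stump_height = 0.3)
  )
  out <- apply_no_charcoal(stems, links)
  expect_equal(sum(out$alive & !out$cut), 2)              # +1 live stem
  expect_false(out$cut[2])
  expect_equal(out$diameter[2], 18, tolerance = 1e-12)    # reconstructed DBH
  expect_equal(out$pom[2], 1.3)
  expect_true(out$cut[3])                                 # other species untouched
  expect_identical(stems$cut, c(FALSE, TRUE, TRUE))       # input unmodified

  # a plot with no cut stems is returned unchanged
  clean <- make_stems("p1", "C. mopane", 20)
  expect_equal(apply_no_charcoal(clean, links)$diameter, clean$diameter)
})

test_that("unreconstructable stumps are skipped and counted", {
  links <- toy_links()
  stems <- make_stems("p1", "C. mopane", NA_real_, pom = NA_real_,
                      alive = FALSE, cut = TRUE, stump_height = NA_real_)
  expect_message(out <- apply_no_charcoal(stems, links), "not restored")
  expect_equal(attr(out, "skipped"), 1)
  expect_true(out$cut[1])
})

test_that("the total-charcoal counterfactual cuts the charcoal band selectively", {
  links <- toy_links()
  stems <- dplyr::bind_rows(
    make_stems("p1", "C. mopane", 20),   # in band: cut
    make_stems("p1", "C. mopane", 8),    # below 10 cm: spared
    make_stems("p1", "sp. 02", 30)       # non-charcoal: spared
  )
  out <- apply_total_charcoal(stems, links)
  expect_equal(out$cut, c(TRUE, FALSE, FALSE))
  # stump diameter round-trips to the pre-cut DBH
  expect_equal(reconstruct_stump_dbh(out$diameter[1], out$pom[1]), 20,
               tolerance = 1e-12)

  # no charcoal species: identical plot
  other <- make_stems("p1", "unlinked sp.", 25)
  expect_equal(apply_total_charcoal(other, links), other, ignore_attr = TRUE)

  # charcoal availability after total harvest is exactly zero
  plots <- make_plots("p1")
  expect_equal(plot_service(out, plots, links, "charcoal")$value, 0)
})

test_that("scenario monotonicity holds for every tree service on synthetic plots", {
  ds <- small_dataset()
  plots <- ds$plots
  links <- ds$links
  nc <- apply_no_charcoal(ds$stems, links)
  tc <- apply_total_charcoal(ds$stems, links)
  for (svc in c("charcoal", "firewood", "construction", "food", "medicine")) {
    cur <- plot_service(ds$stems, plots, links, svc)$value
    up <- plot_service(nc, plots, links, svc)$value
    down <- plot_service(tc, plots, links, svc)$value
    expect_true(all(up >= cur - 1e-9), label = paste(svc, "no_charcoal"))
    expect_true(all(down <= cur + 1e-9), label = paste(svc, "total_charcoal"))
  }
})

test_that("total then no charcoal round-trips the restored charcoal stock", {
  ds <- small_dataset()
  links <- ds$links
  # the round trip restores historical stumps too, so it must equal the
  # no-charcoal restoration, and the current stock wherever nothing was cut
  round_trip <- apply_no_charcoal(apply_total_charcoal(ds$stems, links), links)
  restored <- apply_no_charcoal(ds$stems, links)
  back <- plot_service(round_trip, ds$plots, links, "charcoal")$value
  full <- plot_service(restored, ds$plots, links, "charcoal")$value
  expect_equal(back, full, tolerance = 1e-8)

  never_cut <- !ds$plots$plot_id %in% ds$stems$plot_id[ds$stems$cut]
  cur <- plot_service(ds$stems, ds$plots, links, "charcoal")$value
  expect_gt(sum(never_cut), 0)
  expect_equal(back[never_cut], cur[never_cut], tolerance = 1e-8)
})

test_that("food and medicine losses are bounded by the charcoal species overlap", {
  ds <- small_dataset()
  links <- ds$links
  tc <- apply_total_charcoal(ds$stems, links)
  charcoal_sp <- links$species[links$service == "charcoal"]
  for (svc in c("food", "medicine")) {
    sp <- links$species[links$service == svc & !is.na(links$species)]
    cur <- plot_service(ds$stems, ds$plots, links, svc)$value
    after <- plot_service(tc, ds$plots, links, svc)$value
    # stems lost per plot cannot exceed the stems of overlapping species
    overlap_sp <- intersect(sp, charcoal_sp)
    overlap <- plot_service(
      ds$stems[ds$stems$species %in% overlap_sp, ],
      ds$plots, links, svc)$value
    expect_true(all(cur - after <= overlap + 1e-9), label = svc)
  }
})

test_that("percent changes and delta CIs follow the ratio formulas", {
  cur <- tibble::tibble(village = "A", service = "charcoal",
                        value = 100, se = 10)
  same <- tibble::tibble(village = "A", service = "charcoal",
                         value = 100, se = 10)
  eq <- scenario_change(cur, same, "s")
  expect_equal(eq$pct_change, 0)

  gone <- dplyr::mutate(same, value = 0, se = 0)
  expect_equal(scenario_change(cur, gone, "s")$pct_change, -100)

  up <- dplyr::mutate(same, value = 150, se = 10)
  d <- scenario_change(cur, up, "s")
  expect_equal(d$pct_change, 50)
  se_hand <- 100 * sqrt((10 / 100)^2 + (150 * 10 / 100^2)^2)
  expect_equal(d$ci_hi - d$pct_change, 1.96 * se_hand, tolerance = 1e-10)

  # zero current: percent undefined, absolute change still reported
  cur0 <- dplyr::mutate(cur, value = 0, se = 0)
  z <- scenario_change(cur0, up, "s")
  expect_true(is.na(z$pct_change))
  expect_equal(z$absolute_change, 150)
})

test_that("delta-method CI width is within 5% of the Monte-Carlo oracle", {
  cur <- tibble::tibble(village = "A", service = "charcoal",
                        value = 100, se = 10)
  up <- dplyr::mutate(cur, value = 150, se = 10)
  d <- scenario_change(cur, up, "s", method = "delta")
  m <- scenario_change(cur, up, "s", method = "mc", n_draws = 1e5, seed = 4)
  expect_lt(abs((d$ci_hi - d$ci_lo) - (m$ci_hi - m$ci_lo)) /
              (m$ci_hi - m$ci_lo), 0.05)
})

test_that("full scenario pipeline: total charcoal is a 100% loss everywhere", {
  rep <- full_report()
  tc <- dplyr::filter(rep$scenarios, scenario == "total_charcoal",
                      service == "charcoal")
  expect_equal(nrow(tc), 7)
  expect_equal(tc$pct_change, rep(-100, 7))

  nc <- dplyr::filter(rep$scenarios, scenario == "no_charcoal",
                      service == "charcoal")
  expect_true(all(nc$pct_change >= -1e-9))
  # heavier historical cutting (post-boom) shows the larger reconstruction gain
  classes <- rep$analysis$class_map
  nc <- dplyr::left_join(nc, classes, by = "village")
  expect_gt(mean(nc$pct_change[nc$class == "post-boom"]),
            mean(nc$pct_change[nc$class == "pre-boom"]))
})
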