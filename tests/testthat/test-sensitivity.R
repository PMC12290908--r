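test_that("bundle paths resolve scalars, table cells, and report bad names", {
  b <- generate_fixture(1, "paper_like")
  expect_equal(rrmcea:::bundle_get(b, "costs.rrm"), 8000)
  expect_equal(rrmcea:::bundle_get(b, "utilities.decrements.rrm"), 0.05)
  expect_equal(rrmcea:::bundle_get(b, "costs.treatment.subsequent_year.stage4"),
               7500)
  b2 <- rrmcea:::bundle_set(b, "costs.treatment.subsequent_year.stage4", 9000)
  expect_equal(rrmcea:::bundle_get(b2, "costs.treatment.subsequent_year.stage4"),
               9000)
  b3 <- rrmcea:::bundle_set(b, "strategy.prevention_uptake", 0.2)
  expect_equal(b3$strategy$prevention_uptake, 0.2)
  expect_equal(b3$strategy$hr_tamoxifen, b$strategy$hr_tamoxifen)
  expect_error(rrmcea:::bundle_get(b, "costs.nonexistent"),
               class = "rrmcea_config_error")
  expect_error(rrmcea:::bundle_get(b, "tables.incidence"),
               class = "rrmcea_config_error")
})

test_that("default specs follow the range conventions", {
  b <- generate_fixture(1, "paper_like")
  sp <- default_param_specs(b)
  gam <- sp[sp$distribution == "GAMMA", ]
  expect_true(all(abs(gam$low - 0.7 * gam$point) < 1e-9))
  expect_true(all(abs(gam$high - 1.3 * gam$point) < 1e-9))
  others <- sp[sp$distribution %in% c("BETA", "LOGNORMAL") &
                 sp$name != "strategy.rrm_hazard_ratio", ]
  expect_true(all(abs(others$low - 0.9 * others$point) < 1e-9))
  expect_true(all(others$high <= pmin(1.1 * others$point, 1) + 1e-9))
  # the surgery effect uses its published range
  rrm <- sp[sp$name == "strategy.rrm_hazard_ratio", ]
  expect_equal(c(rrm$low, rrm$point, rrm$high), c(0.02, 0.09, 0.38))
  expect_true(all(sp$low <= sp$point & sp$point <= sp$high))
})

test_that("tornado entries collapse to zero spread for fixed parameters", {
  b <- generate_fixture(1, "paper_like")
  specs <- tibble::tibble(
    name = c("costs.rrm", "costs.mri"),
    point = c(8000, 300), low = c(8000, 300), high = c(8000, 300),
    distribution = "GAMMA", se = c(800, 30))
  tor <- owsa(b, specs, 0.34, 30)
  expect_equal(tor$spread, c(0, 0))
  expect_equal(tor$icer_at_low, tor$icer_at_high)
})

test_that("a dearer surgery worsens the tornado ICER monotonically", {
  b <- generate_fixture(1, "paper_like")
  specs <- tibble::tibble(name = "costs.rrm", point = 8000,
                          low = 0.7 * 8000, high = 1.3 * 8000,
                          distribution = "GAMMA", se = 800)
  tor <- owsa(b, specs, 0.34, 30)
  expect_gt(tor$icer_at_high, tor$icer_base)
  expect_lt(tor$icer_at_low, tor$icer_base)
  # entries come back sorted by spread
  sp2 <- dplyr::bind_rows(specs, tibble::tibble(
    name = "costs.mammography", point = 50, low = 35, high = 65,
    distribution = "GAMMA", se = 5))
  tor2 <- owsa(b, sp2, 0.34, 30)
  expect_true(!is.unsorted(rev(tor2$spread)))
  expect_equal(tor2$name[1], "costs.rrm")
})

test_that("parameter draws honour their distribution families", {
  b <- generate_fixture(1, "paper_like")
  sp <- default_param_specs(b)
  # zero-dispersion limit returns the point values exactly
  sp0 <- dplyr::mutate(sp, se = 0)
  set.seed(1)
  expect_equal(unname(draw_parameters(sp0)), sp$point)
  # FIXED rows never move even with positive se
  set.seed(2)
  v <- draw_parameters(sp)
  fixed <- sp$distribution == "FIXED"
  expect_equal(unname(v[fixed]), sp$point[fixed])
  # gamma moment match: mean of many draws near the target mean
  gspec <- tibble::tibble(name = "costs.rrm", point = 1000, low = 700,
                          high = 1300, distribution = "GAMMA", se = 100)
  set.seed(3)
  draws <- replicate(10000, draw_parameters(gspec))
  expect_lt(abs(mean(draws) - 1000), 3 * 100 / sqrt(10000))
  # beta draws stay inside [0, 1] even with an infeasible se
  bspec <- tibble::tibble(name = "strategy.prevention_uptake", point = 0.163,
                          low = 0.1, high = 0.3, distribution = "BETA",
                          se = 0.9)
  set.seed(4)
  bd <- replicate(2000, draw_parameters(bspec))
  expect_true(all(bd >= 0 & bd <= 1))
  # lognormal utility draws truncate at 1
  lspec <- tibble::tibble(name = "utilities.survivor", point = 0.95,
                          low = 0.85, high = 1, distribution = "LOGNORMAL",
                          se = 0.3)
  set.seed(5)
  ld <- replicate(2000, draw_parameters(lspec))
  expect_true(all(ld <= 1))
  expect_error(draw_parameters(dplyr::mutate(gspec, se = -1)),
               class = "rrmcea_spec_error")
})

test_that("PSA is bit-reproducible and its CEAC behaves", {
  b <- generate_fixture(1, "paper_like")
  sp <- default_param_specs(b)
  p1 <- psa(b, sp, n = 40, seed = 7, lifetime_risk = 0.34, start_age = 30)
  p2 <- psa(b, sp, n = 40, seed = 7, lifetime_risk = 0.34, start_age = 30)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  expect_false(identical(
    p1$draws,
    psa(b, sp, n = 40, seed = 8, lifetime_risk = 0.34, start_age = 30)$draws))
  # all deltas positive here, so the CEAC must be non-decreasing
  expect_true(all(p1$draws$delta_qaly > 0))
  expect_true(!is.unsorted(p1$ceac$probability))
  # CEAC at wtp 0 equals the fraction of cost-saving draws
  expect_equal(p1$ceac$probability[p1$ceac$wtp == 0],
               mean(p1$draws$delta_cost < 0))
  g <- glance(p1)
  expect_equal(g$n, 40L)
  expect_equal(tidy(p1), p1$ceac)
})

test_that("all-FIXED specs give a degenerate step-function CEAC", {
  b <- generate_fixture(1, "paper_like")
  sp <- dplyr::mutate(default_param_specs(b), distribution = "FIXED")
  p <- psa(b, sp, n = 5, seed = 1, lifetime_risk = 0.34, start_age = 30)
  expect_true(all(p$ceac$probability %in% c(0, 1)))
  det <- evaluate_scenario(b, 0.34, 30)$icer$icer
  expect_equal(p$ceac$probability, as.numeric(p$ceac$wtp > det))
})

test_that("the median PSA ICER approaches the deterministic ICER as dispersion shrinks", {
  b <- generate_fixture(1, "paper_like")
  det <- evaluate_scenario(b, 0.34, 30)$icer$icer
  sp_small <- dplyr::mutate(default_param_specs(b), se = se * 0.01)
  p <- psa(b, sp_small, n = 60, seed = 9, lifetime_risk = 0.34,
           start_age = 30)
  med <- median(p$draws$delta_cost / p$draws$delta_qaly)
  expect_lt(abs(med - det) / det, 0.05)
})
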