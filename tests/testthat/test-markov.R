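test_that("stage distribution context follows the screening window", {
  d <- toy_disease(stage_dist = c(0.1, 0.35, 0.35, 0.15, 0.05),
                   stage_dist_screened = c(0.25, 0.40, 0.25, 0.08, 0.02))
  sched <- screening_schedule(0.25)  # window 40-69
  expect_equal(stage_distribution_at(45, sched, d), d$stage_dist_screened)
  expect_equal(stage_distribution_at(35, sched, d), d$stage_dist_general)
  expect_equal(stage_distribution_at(70, sched, d), d$stage_dist_general)
  expect_equal(stage_distribution_at(45, NULL, d), d$stage_dist_general)
  # both contexts equal: age-independent
  d2 <- toy_disease(stage_dist = c(0.2, 0.2, 0.2, 0.2, 0.2))
  for (a in c(30, 45, 75)) {
    expect_equal(stage_distribution_at(a, sched, d2), d2$stage_dist_general)
  }
  d$stage_dist_screened <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(stage_distribution_at(45, sched, d),
               class = "rrmcea_validation_error")
})

test_that("two-cycle toy cohort matches hand enumeration", {
  ages <- 20:79
  inc <- const_table(ages, 0.1)
  mort <- const_table(ages, 0)
  cfg <- model_config(30, horizon_age = 80)
  q <- stage_mat(0)
  q["stage1", 1] <- 0.2  # first-year death probability only
  d <- toy_disease(q = q)
  tr <- run_cohort(toy_screen_strategy(), toy_profile(inc), d, cfg, mort)
  # cycle-2 occupancy: healthy 0.81, stage1 year-1 0.09, year-2 0.08, dead 0.02
  expect_equal(unname(tr$states["2", "healthy"]), 0.81, tolerance = 1e-12)
  expect_equal(unname(tr$states["2", "stage1_y1"]), 0.09, tolerance = 1e-12)
  expect_equal(unname(tr$states["2", "stage1_y2"]), 0.1 * 0.8,
               tolerance = 1e-12)
  expect_equal(unname(tr$states["2", "dead_bc"]), 0.1 * 0.2,
               tolerance = 1e-12)
  # of the 0.09 in year 1, 0.018 die the next cycle
  expect_equal(unname(tr$states["3", "dead_bc"] - tr$states["2", "dead_bc"]),
               0.09 * 0.2, tolerance = 1e-12)
})

test_that("degenerate cohorts behave exactly", {
  ages <- 20:79
  zero <- const_table(ages, 0)
  cfg <- model_config(30)
  d <- toy_disease()
  # zero incidence, zero mortality: everyone healthy, 50 undiscounted LY
  tr <- run_cohort(toy_screen_strategy(), toy_profile(zero), d, cfg, zero)
  expect_true(all(tr$states[, "healthy"] == 1))
  b <- generate_fixture(1, "paper_like")
  econ <- summarize_economics(tr, b$costs, list(
    norms = const_table(ages, 1),
    state = b$utilities$state, distant_recurrence = 0.6, survivor = 0.95,
    decrements = list(rrm = 0, screening = 0, false_positive = 0,
                      prevention = 0)),
    discount_rate_costs = 0, discount_rate_effects = 0)
  expect_equal(econ$undiscounted_ly, 50)
  expect_equal(econ$undiscounted_qaly, 50)
  # a perfect surgery removes all breast cancer
  pr <- risk_profile(b$tables$incidence, 0.50)
  tr2 <- run_cohort(toy_rrm_strategy(30, hr = 0), pr, disease_params(b),
                    cfg, b$tables$mortality)
  expect_equal(sum(dplyr::select(tr2$flows, dplyr::starts_with("diag_"))), 0)
  expect_equal(unname(tr2$states[51, "dead_bc"]), 0)
})

test_that("cohort occupancy is conserved to 1e-12 on random fixtures", {
  for (seed in 1:15) {
    b <- generate_fixture(seed, "random_valid")
    tr <- run_bundle_arm(b, 0.25 + 0.02 * (seed %% 5), 30 + 2 * (seed %% 4),
                         if (seed %% 2) "screen" else "rrm")
    expect_lt(max(abs(rowSums(tr$states) - 1)), 1e-12)
    # dead states are absorbing
    expect_true(all(diff(tr$states[, "dead_bc"]) >= 0))
    expect_true(all(diff(tr$states[, "dead_other"]) >= 0))
    expect_true(all(tr$states >= 0))
  }
})

test_that("cohort propagation matches exhaustive path enumeration", {
  set.seed(7)
  ages <- 20:79
  cfg3 <- model_config(30, horizon_age = 33)
  for (rep in 1:5) {
    p_inc <- runif(1, 0, 0.3)
    p_m <- runif(1, 0, 0.3)
    sd3 <- c(runif(3), 0, 0); sd3 <- sd3 / sum(sd3)
    names(sd3) <- c("dcis", "stage1", "stage2", "stage3", "stage4")
    q <- stage_mat(runif(5, 0, 0.4))
    rd <- stage_mat(runif(5, 0, 0.3))
    qd <- runif(1, 0, 0.5)
    d <- toy_disease(stage_dist = sd3, q = q, rd = rd, qd = qd)
    inc <- const_table(ages, p_inc)
    mort <- const_table(ages, p_m)
    tr <- run_cohort(toy_screen_strategy(), toy_profile(inc), d, cfg3, mort)
    oracle <- enumerate_cohort_oracle(rep(p_inc, 3), rep(p_m, 3), sd3,
                                      q, rd, qd, 3)
    expect_equal(max(abs(tr$states - oracle)), 0, tolerance = 1e-12)
  }
})

test_that("with routine screening and no prevention the cohort reproduces the life-table risk", {
  b <- generate_fixture(1, "paper_like")
  for (start_age in c(30, 45)) {
    pr <- risk_profile(b$tables$incidence, 0.16)  # SUB_NICE, no prevention
    cfg <- model_config(start_age)
    tr <- run_cohort(toy_screen_strategy(screening_schedule(0.16)), pr,
                     disease_params(b), cfg, b$tables$mortality)
    cum_inc <- sum(dplyr::select(tr$flows, dplyr::starts_with("diag_")))
    expected <- cumulative_lifetime_risk(pr$scaled_incidence,
                                         b$tables$mortality, start_age, 80)
    expect_equal(cum_inc, expected, tolerance = 1e-9)
  }
})

test_that("cumulative incidence responds monotonically to every risk lever", {
  b <- generate_fixture(3, "random_valid")
  cum_inc <- function(tr) {
    sum(dplyr::select(tr$flows, dplyr::starts_with("diag_")))
  }
  # increasing hazard ratio
  incs <- sapply(c(0.2, 0.3, 0.4, 0.5), function(r) {
    cum_inc(run_bundle_arm(b, r, 30, "screen"))
  })
  expect_true(all(diff(incs) > 0))
  # stronger surgery effect lowers incidence
  pr <- risk_profile(b$tables$incidence, 0.4)
  cfg <- model_config(30)
  rrm_incs <- sapply(c(0, 0.09, 0.3, 1), function(hr) {
    cum_inc(run_cohort(toy_rrm_strategy(30, hr), pr, disease_params(b), cfg,
                       b$tables$mortality))
  })
  expect_true(all(diff(rrm_incs) > 0))
  # higher prevention uptake and stronger (smaller) prevention HR lower incidence
  screen_inc <- function(uptake, hr) {
    st <- make_strategies(pr, 30, prevention_args = list(
      uptake = uptake, hr_tamoxifen = hr, hr_anastrozole = hr))
    cum_inc(run_cohort(st$screen, pr, disease_params(b), cfg,
                       b$tables$mortality))
  }
  by_uptake <- sapply(c(0, 0.163, 0.5, 1), screen_inc, hr = 0.6)
  expect_true(all(diff(by_uptake) < 0))
  by_hr <- sapply(c(0.4, 0.6, 0.8, 1), screen_inc, uptake = 0.5)
  expect_true(all(diff(by_hr) > 0))
})

test_that("trace accessors expose tidy views", {
  b <- generate_fixture(1, "paper_like")
  tr <- run_bundle_arm(b, 0.34, 30, "screen")
  tall <- tidy(tr)
  expect_named(tall, c("cycle", "age", "state", "occupancy"))
  expect_equal(nrow(tall), 51 * 105)
  g <- glance(tr)
  expect_equal(g$strategy, "SCREEN")
  expect_equal(g$cycles, 50)
  tmp <- withr::local_tempfile(fileext = ".csv")
  wide <- write_trace_csv(tr, tmp)
  expect_equal(nrow(wide), 50)
  expect_true(file.exists(tmp))
})
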