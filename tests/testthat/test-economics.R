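test_that("discount factors follow NICE convention", {
  expect_equal(discount_factor(0.035, 0), 1)
  expect_equal(discount_factor(0, 17), 1)
  expect_equal(round(discount_factor(0.035, 1), 5), 0.96618)
  expect_equal(discount_factor(0.035, 0:3), 1.035^-(0:3))
  expect_error(discount_factor(-0.01, 1), class = "rrmcea_domain_error")
  expect_error(discount_factor(0.035, -1), class = "rrmcea_domain_error")
})

test_that("utility age adjustment is multiplicative", {
  norms <- age_rate_table(30:40, seq(0.95, 0.85, length.out = 11))
  expect_equal(age_adjusted_utility(30, 1, norms), 0.95)
  expect_equal(age_adjusted_utility(35, 0.8,
                                    const_table(30:40, 1)), 0.8)
  expect_equal(age_adjusted_utility(30, 0.8, const_table(30:40, 0.9)), 0.72)
  expect_error(age_adjusted_utility(50, 0.8, norms),
               class = "rrmcea_coverage_error")
})

test_that("pathology-weighted costs are convex combinations", {
  costs <- tibble::tibble(stage = c("stage1", "stage2"),
                          er_positive = c(100, 1000),
                          er_negative = c(300, 1000))
  out <- weight_treatment_costs(costs, c(er_positive = 0.5,
                                         er_negative = 0.5))
  expect_equal(out$cost, c(200, 1000))
  # degenerate mix picks one subtype; equal costs are mix-independent
  out1 <- weight_treatment_costs(costs, c(er_positive = 1, er_negative = 0))
  expect_equal(out1$cost, c(100, 1000))
  out2 <- weight_treatment_costs(costs, c(er_positive = 0.123,
                                          er_negative = 0.877))
  expect_equal(out2$cost[2], 1000)
  expect_error(weight_treatment_costs(costs, c(er_positive = 0.5,
                                               er_negative = 0.6)),
               class = "rrmcea_validation_error")
})

test_that("discounted life-years reduce to the geometric series", {
  ages <- 20:79
  zero <- const_table(ages, 0)
  cfg <- model_config(30)
  tr <- run_cohort(toy_screen_strategy(), toy_profile(zero), toy_disease(),
                   cfg, zero)
  b <- generate_fixture(1, "paper_like")
  util1 <- list(norms = const_table(ages, 1), state = b$utilities$state,
                distant_recurrence = 0.6, survivor = 0.95,
                decrements = list(rrm = 0, screening = 0,
                                  false_positive = 0, prevention = 0))
  costs0 <- b$costs
  costs0$mammography <- 0
  econ <- summarize_economics(tr, costs0, util1, 0.035, 0.035)
  expect_equal(econ$discounted_ly, sum(1.035^-(0:49)), tolerance = 1e-12)
  expect_equal(round(econ$discounted_ly, 2), 24.28)
  expect_equal(econ$discounted_qaly, econ$discounted_ly, tolerance = 1e-12)
})

test_that("isolated events are costed at their discounted unit price", {
  ages <- 20:79
  zero <- const_table(ages, 0)
  cfg <- model_config(30)
  b <- generate_fixture(1, "paper_like")
  # healthy cohort, single mammogram at 50 under the SUB_NICE-like schedule
  sched <- structure(list(tier = "SUB_NICE", events = tibble::tibble(
    age = 50L, modality = "mammography")), class = "bc_schedule")
  d <- toy_disease()  # fp rate 0
  tr <- run_cohort(toy_screen_strategy(sched), toy_profile(zero), d, cfg,
                   zero)
  costs0 <- rapply(b$costs, function(x) 0, how = "replace",
                   classes = "numeric")
  costs0$treatment <- dplyr::mutate(b$costs$treatment,
                                    dplyr::across(-stage, ~0))
  costs0$mammography <- 123
  util1 <- list(norms = const_table(ages, 1), state = b$utilities$state,
                distant_recurrence = 0.6, survivor = 0.95,
                decrements = list(rrm = 0, screening = 0,
                                  false_positive = 0, prevention = 0))
  econ <- summarize_economics(tr, costs0, util1, 0.035, 0.035)
  expect_equal(econ$discounted_cost, 123 * discount_factor(0.035, 20),
               tolerance = 1e-12)
  expect_equal(econ$undiscounted_cost, 123)
})

test_that("discounted totals fall as the discount rate rises", {
  b <- generate_fixture(1, "paper_like")
  tr <- run_bundle_arm(b, 0.34, 30, "screen")
  rates <- c(0, 0.015, 0.035, 0.06)
  res <- lapply(rates, function(r) {
    summarize_economics(tr, b$costs, b$utilities, r, r)
  })
  costs <- sapply(res, `[[`, "discounted_cost")
  qalys <- sapply(res, `[[`, "discounted_qaly")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
  # discounted never exceeds undiscounted
  for (x in res) {
    expect_lte(x$discounted_cost, x$undiscounted_cost)
    expect_lte(x$discounted_qaly, x$undiscounted_qaly)
    expect_lte(x$discounted_ly, x$undiscounted_ly)
  }
})

test_that("adding a screening event raises cost and lowers QALYs, disease held fixed", {
  b <- generate_fixture(1, "paper_like")
  # make both stage-distribution contexts identical so the disease course
  # cannot differ between schedules
  b$disease$stage_dist_screened <- b$disease$stage_dist_general
  pr <- risk_profile(b$tables$incidence, 0.25)
  cfg <- model_config(30)
  econ_for <- function(sched) {
    tr <- run_cohort(toy_screen_strategy(sched), pr, disease_params(b), cfg,
                     b$tables$mortality)
    summarize_economics(tr, b$costs, b$utilities)
  }
  base <- econ_for(screening_schedule(0.16))     # triennial 50-68
  more <- econ_for(screening_schedule(0.25))     # + annual 40-49
  expect_gt(more$discounted_cost, base$discounted_cost)
  expect_lt(more$discounted_qaly, base$discounted_qaly)
  expect_equal(more$cumulative_bc_incidence, base$cumulative_bc_incidence)
})

test_that("economic summaries expose tidy and glance views", {
  b <- generate_fixture(1, "paper_like")
  tr <- run_bundle_arm(b, 0.34, 30, "rrm")
  econ <- summarize_economics(tr, b$costs, b$utilities)
  expect_s3_class(econ, "bc_econ")
  long <- tidy(econ)
  expect_named(long, c("strategy", "measure", "value"))
  expect_equal(nrow(long), 8)
  expect_equal(glance(econ)$strategy, "RRM")
  expect_lte(econ$cumulative_bc_death, econ$cumulative_bc_incidence)
})
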