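#' Discount factor
#'
#' `(1 + rate)^(-years_since_start)`. NICE-recommended 3.5% per year is the
#' package default elsewhere.
#'
#' @param rate Annual discount rate (>= 0).
#' @param years_since_start Years elapsed since model start (>= 0).
#' @return Discount factor in (0, 1\].
#' @examples
#' discount_factor(0.035, 1)  # 0.96618
#' @export
discount_factor <- function(rate, years_since_start) {
  if (any(rate < 0)) abort_rrmcea("rate must be >= 0", "rrmcea_domain_error")
  if (any(years_since_start < 0)) {
    abort_rrmcea("years_since_start must be >= 0", "rrmcea_domain_error")
  }
  (1 + rate)^(-years_since_start)
}

#' Age-adjusted health-state utility (multiplicative method)
#'
#' Multiplies the state utility by the age-specific population norm, so that
#' the healthy state at a given age scores the norm and diseased states score
#' proportionally less.
#'
#' @param age Age in years.
#' @param state_utility State utility in \[0, 1\].
#' @param norms Rate table of population utility norms by age.
#' @return Utility in \[0, 1\].
#' @export
age_adjusted_utility <- function(age, state_utility, norms) {
  check_probability(state_utility, "state_utility")
  norm <- rate_window(validate_age_rate_table(norms, "utility norms"),
                      age, age + 1L, "utility norms")
  norm * state_utility
}

#' Pathology-mix weighted treatment costs
#'
#' Convex combination of per-subtype treatment costs, one weight per subtype
#' column. Used to fold the proportions of ER-positive, ERBB2-positive,
#' node-positive and premenopausal cancers into a single expected cost per
#' stage.
#'
#' @param subtype_costs Data frame whose first column is `stage` and whose
#'   remaining columns are per-subtype costs.
#' @param pathology_mix Named numeric weights over those subtype columns,
#'   each in \[0, 1\], summing to 1.
#' @return Tibble with columns `stage`, `cost`.
#' @examples
#' weight_treatment_costs(
#'   tibble::tibble(stage = "stage1", a = 100, b = 300),
#'   c(a = 0.5, b = 0.5))  # 200
#' @export
weight_treatment_costs <- function(subtype_costs, pathology_mix) {
  check_probability(pathology_mix, "pathology_mix")
  if (abs(sum(pathology_mix) - 1) > 1e-9) {
    abort_rrmcea("pathology_mix weights must sum to 1",
                 "rrmcea_validation_error")
  }
  cols <- names(pathology_mix)
  if (!all(cols %in% names(subtype_costs))) {
    abort_rrmcea("pathology_mix names must match subtype cost columns",
                 "rrmcea_validation_error")
  }
  mat <- as.matrix(subtype_costs[cols])
  tibble::tibble(stage = subtype_costs$stage,
                 cost = as.vector(mat %*% pathology_mix))
}

#' Discounted economic summary of a cohort trace
#'
#' Attaches unit costs and utilities to every state-year and event flow of a
#' trace and reports discounted (and undiscounted) totals.
#'
#' Per cycle, costs are: screens and false positives (recall plus a biopsy
#' fraction), the RRM procedure in the surgery year, prevention drug-years
#' (takers only), stage treatment costs (first tunnel year at the first-year
#' cost, subsequent years at the subsequent cost), an annual
#' distant-recurrence cost, a per-event local-recurrence cost, and terminal
#' care charged in the cycle of breast-cancer death. QALYs are occupancy
#' times age-adjusted state utility, minus event disutilities: screening
#' (1/52 year), false positives (5/52 year), RRM (surgery year) and
#' prevention (each treated year). A cycle utility pushed below zero by
#' decrements is clamped to zero with a warning.
#'
#' @param trace A `bc_trace` from [run_cohort()].
#' @param costs Cost table (list; see [generate_fixture()] for the schema).
#' @param utilities Utility table (list): `norms` rate table, `state` tibble
#'   (`stage`, `first_year`, `subsequent`), scalars `distant_recurrence`,
#'   `survivor`, and `decrements` (`rrm`, `screening`, `false_positive`,
#'   `prevention`).
#' @param discount_rate_costs,discount_rate_effects Annual discount rates
#'   (default 0.035 each; the tornado varies them separately).
#' @return One-row tibble of class `bc_econ`: `strategy`, `discounted_cost`,
#'   `discounted_qaly`, `discounted_ly`, `undiscounted_cost`,
#'   `undiscounted_qaly`, `undiscounted_ly`, `cumulative_bc_incidence`,
#'   `cumulative_bc_death`.
#' @export
summarize_economics <- function(trace, costs, utilities,
                                discount_rate_costs = 0.035,
                                discount_rate_effects = 0.035) {
  H <- nrow(trace$flows)
  ages <- trace$flows$age
  dc <- discount_factor(discount_rate_costs, 0:(H - 1))
  de <- discount_factor(discount_rate_effects, 0:(H - 1))
  st <- trace$states[seq_len(H), , drop = FALSE]
  fl <- trace$flows
  ti <- tunnel_index()
  stages <- bc_stages()

  # occupancy blocks
  occ_y1 <- st[, ti[, 1], drop = FALSE]                      # H x 5
  occ_sub <- sapply(seq_along(stages), function(s) {
    rowSums(st[, ti[s, 2:20], drop = FALSE])
  })                                                          # H x 5
  occ_dist <- st[, "distant_recurrence"]
  occ_surv <- st[, "long_term_survivor"]
  occ_healthy <- st[, "healthy"]
  alive <- occ_healthy + rowSums(occ_y1) + rowSums(occ_sub) +
    occ_dist + occ_surv

  # ---- costs ----
  tr <- costs$treatment[match(stages, costs$treatment$stage), ]
  death_by_stage <- as.matrix(fl[paste0("bc_death_", stages)])
  drug <- ifelse(ages < trace$config$menopause_age,
                 costs$tamoxifen_annual, costs$anastrozole_annual)
  cost_cycle <-
    fl$screens_mammography * costs$mammography +
    fl$screens_mri * costs$mri +
    fl$false_positives * (costs$fp_recall +
                            costs$fp_biopsy_fraction * costs$fp_biopsy) +
    fl$rrm_events * costs$rrm +
    fl$prevention_treated_py * drug +
    occ_y1 %*% tr$first_year +
    occ_sub %*% tr$subsequent_year +
    occ_dist * costs$distant_recurrence_annual +
    fl$local_recurrences * costs$local_recurrence_event +
    death_by_stage %*% tr$terminal +
    fl$bc_death_distant * tr$terminal[match("stage4", tr$stage)]
  cost_cycle <- as.vector(cost_cycle)

  # ---- QALYs ----
  norms <- rate_window(validate_age_rate_table(utilities$norms,
                                               "utility norms"),
                       trace$config$start_age, trace$config$horizon_age,
                       "utility norms")
  su <- utilities$state[match(stages, utilities$state$stage), ]
  util_states <- occ_healthy * 1 +
    occ_y1 %*% su$first_year +
    occ_sub %*% su$subsequent +
    occ_dist * utilities$distant_recurrence +
    occ_surv * utilities$survivor
  util_states <- as.vector(util_states) * norms
  decr <- utilities$decrements
  util_events <-
    (fl$screens_mammography + fl$screens_mri) * decr$screening / 52 +
    fl$false_positives * decr$false_positive * 5 / 52 +
    fl$rrm_events * decr$rrm +
    fl$prevention_treated_py * decr$prevention
  qaly_cycle <- util_states - util_events
  if (any(qaly_cycle < 0)) {
    warning("per-cycle utility below 0 after decrements; clamped to 0")
    qaly_cycle <- pmax(qaly_cycle, 0)
  }

  out <- tibble::tibble(
    strategy = trace$strategy_kind,
    discounted_cost = sum(cost_cycle * dc),
    discounted_qaly = sum(qaly_cycle * de),
    discounted_ly = sum(alive * de),
    undiscounted_cost = sum(cost_cycle),
    undiscounted_qaly = sum(qaly_cycle),
    undiscounted_ly = sum(alive),
    cumulative_bc_incidence = sum(as.matrix(fl[paste0("diag_", stages)])),
    cumulative_bc_death = sum(death_by_stage) + sum(fl$bc_death_distant)
  )
  class(out) <- c("bc_econ", class(out))
  out
}
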