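#' Incremental cost-effectiveness ratio
#'
#' Deltas are `alternative - reference`. Dominance is classified before any
#' division: the alternative dominates (`ALT_DOMINANT`) if it is no more
#' costly and more effective (or cheaper and no less effective); it is
#' dominated (`ALT_DOMINATED`) if the reverse. Otherwise
#' `icer = delta_cost / delta_qaly`.
#'
#' @param reference,alternative `bc_econ` rows (reference = screening arm,
#'   alternative = RRM arm in the package's main comparison).
#' @return Object of class `bc_icer`: list with `delta_cost`, `delta_qaly`,
#'   `icer` (NA under dominance), `dominance`.
#' @export
icer <- function(reference, alternative) {
  dc <- alternative$discounted_cost - reference$discounted_cost
  dq <- alternative$discounted_qaly - reference$discounted_qaly
  dominance <- if (dq > 0 && dc <= 0 || dq >= 0 && dc < 0) {
    "ALT_DOMINANT"
  } else if (dq < 0 && dc >= 0 || dq <= 0 && dc > 0) {
    "ALT_DOMINATED"
  } else {
    "NONE"
  }
  value <- if (dominance == "NONE" && dq != 0) dc / dq else NA_real_
  structure(list(delta_cost = dc, delta_qaly = dq, icer = value,
                 dominance = dominance),
            class = "bc_icer")
}

#' @export
print.bc_icer <- function(x, ...) {
  if (x$dominance == "NONE") {
    cat(sprintf(
      "<bc_icer> Δcost %.0f | ΔQALY %.4f | ICER %.0f per QALY\n",
      x$delta_cost, x$delta_qaly, x$icer))
  } else {
    cat(sprintf("<bc_icer> Δcost %.0f | ΔQALY %.4f | %s\n",
                x$delta_cost, x$delta_qaly, x$dominance))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `delta_qaly * wtp - delta_cost`; positive exactly when the alternative is
#' cost-effective at willingness-to-pay `wtp` (for `delta_qaly > 0`,
#' equivalent to ICER < wtp).
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @param wtp Willingness to pay per QALY (>= 0).
#' @return Net monetary benefit in the cost currency.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) abort_rrmcea("wtp must be >= 0", "rrmcea_domain_error")
  delta_qaly * wtp - delta_cost
}

#' Evaluate one age-by-risk scenario
#'
#' Runs both comparator arms of the model for a given assumed lifetime risk
#' and start age, and returns their economic summaries with the incremental
#' comparison (RRM vs screening).
#'
#' @param bundle Parameter bundle (see [generate_fixture()]).
#' @param lifetime_risk Assumed lifetime breast-cancer risk in (0, 1).
#' @param start_age Cohort start / surgery age in \[30, 60\].
#' @return List with `screen` and `rrm` (`bc_econ` rows), `icer`
#'   (`bc_icer`), `profile`, `strategies`.
#' @export
evaluate_scenario <- function(bundle, lifetime_risk, start_age) {
  config <- model_config(start_age, bundle$config$horizon_age,
                         bundle$config$menopause_age)
  profile <- risk_profile(bundle$tables$incidence, lifetime_risk,
                          bundle$risk$baseline_lifetime_risk)
  strat <- make_strategies(
    profile, start_age,
    rrm_hazard_ratio = bundle$strategy$rrm_hazard_ratio,
    prevention_args = list(
      uptake = bundle$strategy$prevention_uptake,
      hr_tamoxifen = bundle$strategy$hr_tamoxifen,
      hr_anastrozole = bundle$strategy$hr_anastrozole,
      duration = bundle$strategy$prevention_duration,
      carryover = bundle$strategy$prevention_carryover
    ))
  disease <- c(bundle$disease,
               list(fp_rate_mammography = bundle$strategy$fp_rate_mammography,
                    fp_rate_mri = bundle$strategy$fp_rate_mri))
  run_arm <- function(strategy) {
    tr <- run_cohort(strategy, profile, disease, config,
                     bundle$tables$mortality)
    summarize_economics(tr, bundle$costs, bundle$utilities,
                        bundle$config$discount_rate_costs,
                        bundle$config$discount_rate_effects)
  }
  screen <- run_arm(strat$screen)
  rrm <- run_arm(strat$rrm)
  list(screen = screen, rrm = rrm, icer = icer(screen, rrm),
       profile = profile, strategies = strat)
}

#' Find the lifetime-risk threshold for RRM cost-effectiveness
#'
#' Walks an ascending lifetime-risk grid (default 17% to 50% in 1% steps) and
#' returns the smallest risk at which the ICER of RRM versus screening falls
#' at or below the willingness-to-pay threshold (or RRM dominates). A
#' non-monotone ICER across the grid is reported with a message but still
#' yields the smallest qualifying risk.
#'
#' @param bundle Parameter bundle.
#' @param start_age Cohort start / surgery age.
#' @param wtp Willingness to pay per QALY.
#' @param risk_grid Ascending grid of lifetime risks within \[0.17, 0.50\].
#' @return One-row tibble of class `bc_threshold`: `start_age`, `wtp`,
#'   `threshold_risk` (NA if no grid point qualifies), `icer_at_threshold`,
#'   `criterion`; the full grid scan in attribute `"grid"`.
#' @export
find_threshold <- function(bundle, start_age, wtp,
                           risk_grid = seq(0.17, 0.50, by = 0.01)) {
  if (is.unsorted(risk_grid, strictly = TRUE)) {
    abort_rrmcea("risk_grid must be strictly ascending", "rrmcea_domain_error")
  }
  scan <- purrr::map_dfr(risk_grid, function(r) {
    res <- evaluate_scenario(bundle, r, start_age)
    tibble::tibble(lifetime_risk = r,
                   delta_cost = res$icer$delta_cost,
                   delta_qaly = res$icer$delta_qaly,
                   icer = res$icer$icer,
                   dominance = res$icer$dominance)
  })
  ok <- scan$dominance == "ALT_DOMINANT" |
    (scan$dominance == "NONE" & scan$delta_qaly > 0 & scan$icer <= wtp)
  finite_icer <- scan$icer[!is.na(scan$icer)]
  if (is.unsorted(rev(finite_icer))) {
    message("find_threshold: ICER is not monotone non-increasing across the grid")
  }
  hit <- which(ok)[1]
  out <- tibble::tibble(
    start_age = as.integer(start_age),
    wtp = wtp,
    threshold_risk = if (is.na(hit)) NA_real_ else scan$lifetime_risk[hit],
    icer_at_threshold = if (is.na(hit)) NA_real_ else scan$icer[hit],
    criterion = "ICER_BELOW_WTP"
  )
  class(out) <- c("bc_threshold", class(out))
  attr(out, "grid") <- scan
  out
}

#' Threshold sweep over ages and willingness-to-pay values
#'
#' Recomputes the ICER grid once per age and reads off the threshold for each
#' WTP, mirroring a risk-by-age results table.
#'
#' @param bundle Parameter bundle.
#' @param start_ages Integer vector of start ages.
#' @param wtps Numeric vector of willingness-to-pay values.
#' @param risk_grid Ascending risk grid.
#' @return Tibble with one row per (start_age, wtp): `threshold_risk`,
#'   `icer_at_threshold`; the per-age ICER grids in attribute `"grids"`.
#' @export
threshold_sweep <- function(bundle, start_ages = c(30, 35, 40, 45, 50, 55, 60),
                            wtps = c(20000, 30000),
                            risk_grid = seq(0.17, 0.50, by = 0.01)) {
  grids <- list()
  out <- purrr::map_dfr(start_ages, function(a) {
    th <- find_threshold(bundle, a, wtps[1], risk_grid)
    scan <- attr(th, "grid")
    grids[[as.character(a)]] <<- scan
    purrr::map_dfr(wtps, function(w) {
      ok <- scan$dominance == "ALT_DOMINANT" |
        (scan$dominance == "NONE" & scan$delta_qaly > 0 & scan$icer <= w)
      hit <- which(ok)[1]
      tibble::tibble(
        start_age = as.integer(a), wtp = w,
        threshold_risk = if (is.na(hit)) NA_real_ else scan$lifetime_risk[hit],
        icer_at_threshold = if (is.na(hit)) NA_real_ else scan$icer[hit])
    })
  })
  attr(out, "grids") <- grids
  out
}
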