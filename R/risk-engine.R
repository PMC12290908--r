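#' Lifetime cumulative breast-cancer risk under competing mortality
#'
#' Classic cohort life-table accumulation: the probability of a first
#' breast-cancer diagnosis between `start_age` (inclusive) and `end_age`
#' (exclusive), where each year a still-healthy woman is first exposed to that
#' year's diagnosis probability and the non-diagnosed are then exposed to
#' other-cause death. Formally
#' \deqn{R = \sum_a p_a \prod_{b<a} (1 - p_b)(1 - m_b)}
#' with \eqn{p} annual incidence and \eqn{m} annual all-cause mortality.
#' The UK general-population value of this quantity over ages 20--80 is
#' 10.79%, the baseline everything else in the package is anchored to.
#'
#' @param incidence Rate table of annual diagnosis probabilities.
#' @param all_cause_mortality Rate table of annual other-cause death
#'   probabilities.
#' @param start_age,end_age Age window `[start_age, end_age)`, years.
#' @return A single proportion in \[0, 1\].
#' @examples
#' inc <- age_rate_table(20:79, rep(0.002, 60))
#' mort <- age_rate_table(20:79, rep(0.001, 60))
#' cumulative_lifetime_risk(inc, mort, 20, 80)
#' @export
cumulative_lifetime_risk <- function(incidence, all_cause_mortality,
                                     start_age = 20, end_age = 80) {
  if (end_age <= start_age) {
    abort_rrmcea("end_age must exceed start_age", "rrmcea_domain_error")
  }
  p <- rate_window(validate_age_rate_table(incidence, "incidence"),
                   start_age, end_age, "incidence")
  m <- rate_window(validate_age_rate_table(all_cause_mortality, "mortality"),
                   start_age, end_age, "mortality")
  surv <- cumprod((1 - p) * (1 - m))
  sum(p * c(1, surv[-length(surv)]))
}

#' Lifetime-average hazard ratio for an assumed lifetime risk
#'
#' The log-complement transform used to scale general-population incidence up
#' to an assumed lifetime risk:
#' \deqn{HR = \ln(1 - r_{target}) / \ln(1 - r_{baseline})}
#' e.g. a 25% lifetime risk against the UK baseline of 10.79% gives
#' \eqn{HR = \ln(0.75)/\ln(0.8921) = 2.52}. The ratio is assumed constant
#' across the lifetime.
#'
#' @param target_risk Assumed lifetime risk, in (0, 1).
#' @param baseline_risk General-population lifetime risk, in (0, 1);
#'   default 0.1079.
#' @return Positive scalar hazard ratio, strictly increasing in `target_risk`.
#' @examples
#' hazard_ratio_for_risk(0.25)           # 2.52
#' hazard_ratio_for_risk(0.50, 0.1079)   # 6.07
#' @export
hazard_ratio_for_risk <- function(target_risk, baseline_risk = 0.1079) {
  check_probability(target_risk, "target_risk",
                    allow_zero = FALSE, allow_one = FALSE)
  check_probability(baseline_risk, "baseline_risk",
                    allow_zero = FALSE, allow_one = FALSE)
  log(1 - target_risk) / log(1 - baseline_risk)
}

#' Scale age-specific incidence by a hazard ratio
#'
#' Multiplies each annual probability by `hazard_ratio`, clamping to 1 (with a
#' warning) should the product exceed a probability's range. Probability
#' scaling approximates hazard scaling; for the annual probabilities seen here
#' (well under 0.05) the approximation error on the recomputed lifetime risk
#' is a fraction of a percent.
#'
#' @param incidence Rate table of annual probabilities.
#' @param hazard_ratio Positive scalar multiplier.
#' @return A rate table with scaled values.
#' @export
scale_incidence <- function(incidence, hazard_ratio) {
  if (!is.finite(hazard_ratio) || hazard_ratio < 0) {
    abort_rrmcea("hazard_ratio must be a non-negative number",
                 "rrmcea_domain_error")
  }
  tbl <- validate_age_rate_table(incidence, "incidence")
  scaled <- tbl$value * hazard_ratio
  if (any(scaled > 1)) {
    warning(sprintf("scale_incidence: %d annual probabilities clamped to 1",
                    sum(scaled > 1)))
    scaled <- pmin(scaled, 1)
  }
  tbl$value <- scaled
  tbl
}

#' Calibrate an incidence shape to a target lifetime risk
#'
#' Finds the single multiplier `k` such that `k * shape`, run through
#' [cumulative_lifetime_risk()] against `mortality` over ages 20--80, hits
#' `target` to within 1e-10 (bisection via [stats::uniroot()]). Used by the
#' synthetic fixture so its incidence curve reproduces the 10.79% baseline
#' exactly.
#'
#' @param shape Rate table giving the age pattern of incidence (any positive
#'   scale).
#' @param mortality Rate table of annual all-cause mortality.
#' @param target Target lifetime risk in (0, 1).
#' @param start_age,end_age Risk window, default \[20, 80).
#' @return Calibrated rate table (`shape` scaled by the fitted multiplier),
#'   with the multiplier in attribute `"multiplier"`.
#' @export
calibrate_baseline <- function(shape, mortality, target,
                               start_age = 20, end_age = 80) {
  check_probability(target, "target", allow_zero = FALSE, allow_one = FALSE)
  shape <- validate_age_rate_table(shape, "shape")
  s <- rate_window(shape, start_age, end_age, "shape")
  if (all(s <= 0)) {
    abort_rrmcea("shape must be positive somewhere in the risk window",
                 "rrmcea_calibration_error")
  }
  k_max <- 1 / max(s)  # beyond this the scaled values would need clamping
  risk_at <- function(k) {
    tbl <- shape
    tbl$value <- pmin(tbl$value * k, 1)
    cumulative_lifetime_risk(tbl, mortality, start_age, end_age)
  }
  if (risk_at(k_max) < target) {
    abort_rrmcea(
      sprintf("target %.4f unreachable without clamping (max %.4f)",
              target, risk_at(k_max)),
      "rrmcea_calibration_error"
    )
  }
  root <- stats::uniroot(function(k) risk_at(k) - target,
                         lower = 0, upper = k_max, tol = 1e-14)
  k <- root$root
  out <- shape
  out$value <- out$value * k
  attr(out, "multiplier") <- k
  out
}

#' Build a risk profile for an assumed lifetime risk
#'
#' Bundles the target lifetime risk, the log-complement hazard ratio against
#' the baseline, and the HR-scaled age-specific incidence into one object
#' consumed by the strategy constructors and the cohort engine.
#'
#' @param baseline_incidence Rate table of general-population incidence.
#' @param lifetime_risk_target Assumed lifetime risk in (0, 1).
#' @param baseline_lifetime_risk Baseline lifetime risk (default 0.1079).
#' @return An object of class `bc_risk_profile`: a list with
#'   `lifetime_risk_target`, `baseline_lifetime_risk`, `hazard_ratio`,
#'   `scaled_incidence`.
#' @export
risk_profile <- function(baseline_incidence, lifetime_risk_target,
                         baseline_lifetime_risk = 0.1079) {
  hr <- hazard_ratio_for_risk(lifetime_risk_target, baseline_lifetime_risk)
  structure(
    list(
      lifetime_risk_target = lifetime_risk_target,
      baseline_lifetime_risk = baseline_lifetime_risk,
      hazard_ratio = hr,
      scaled_incidence = scale_incidence(baseline_incidence, hr)
    ),
    class = "bc_risk_profile"
  )
}

#' @export
print.bc_risk_profile <- function(x, ...) {
  cat(sprintf(
    "<bc_risk_profile> target %.1f%% | baseline %.2f%% | hazard ratio %.3f\n",
    100 * x$lifetime_risk_target, 100 * x$baseline_lifetime_risk,
    x$hazard_ratio))
  invisible(x)
}
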