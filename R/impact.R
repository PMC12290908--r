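#' Fraction of population breast-cancer cases arising above a risk threshold
#'
#' Given subgroups of the female population with elevated lifetime risk, the
#' share of all cases they contribute is
#' `sum(prevalence * mean_lifetime_risk) / population_lifetime_risk`.
#' With the published mix — BRCA1/BRCA2 carriers at 0.5% prevalence and 60%
#' mean risk, other high-risk women at 2.5% and 41.8%, population risk 11% —
#' this is `(60% x 0.5% + 41.8% x 2.5%) / 11% = 12.23%`.
#'
#' @param subgroups Data frame with columns `prevalence` (proportion of the
#'   female population) and `mean_lifetime_risk` (proportion), one row per
#'   subgroup. Zero rows give 0.
#' @param population_lifetime_risk Population lifetime risk in (0, 1).
#' @return Proportion in \[0, 1\].
#' @examples
#' case_fraction(
#'   tibble::tibble(prevalence = c(0.005, 0.025),
#'                  mean_lifetime_risk = c(0.60, 0.418)), 0.11)
#' @export
case_fraction <- function(subgroups, population_lifetime_risk) {
  check_probability(population_lifetime_risk, "population_lifetime_risk",
                    allow_zero = FALSE)
  if (nrow(subgroups) == 0) return(0)
  check_probability(subgroups$prevalence, "prevalence")
  check_probability(subgroups$mean_lifetime_risk, "mean_lifetime_risk",
                    allow_zero = FALSE, allow_one = FALSE)
  if (sum(subgroups$prevalence) > 1) {
    abort_rrmcea("subgroup prevalences must sum to at most 1",
                 "rrmcea_validation_error")
  }
  out <- sum(subgroups$prevalence * subgroups$mean_lifetime_risk) /
    population_lifetime_risk
  if (out > 1) {
    abort_rrmcea("case fraction exceeds 1: inconsistent prevalence mix",
                 "rrmcea_validation_error")
  }
  out
}

#' Annual breast-cancer cases prevented by offering RRM above a threshold
#'
#' `annual_cases x case_fraction x reduction`, evaluated at the point
#' reduction and at its lower and upper bounds; the case fraction is carried
#' unrounded and only the final counts are rounded (half away from zero).
#' With the published inputs (58 756 annual UK cases, reduction 0.91 with
#' bounds 0.62--0.98) this gives 6538 (4454--7041) cases, about 11% of the
#' annual total.
#'
#' @inheritParams case_fraction
#' @param annual_cases Annual breast-cancer case count in the population.
#' @param reduction Point risk reduction from RRM in \[0, 1\] (complement of
#'   the residual hazard ratio; 0.91 for a residual HR of 0.09).
#' @param reduction_low,reduction_high Bounds on the reduction,
#'   `low <= reduction <= high`.
#' @return One-row tibble of class `bc_impact`: `case_fraction`,
#'   `prevented_point`, `prevented_low`, `prevented_high` (integer counts),
#'   `prevented_fraction` (unrounded proportion of annual cases).
#' @export
prevented_cases <- function(subgroups, population_lifetime_risk, annual_cases,
                            reduction, reduction_low = reduction,
                            reduction_high = reduction) {
  check_probability(c(reduction, reduction_low, reduction_high), "reduction")
  if (!(reduction_low <= reduction && reduction <= reduction_high)) {
    abort_rrmcea("need reduction_low <= reduction <= reduction_high",
                 "rrmcea_validation_error")
  }
  cf <- case_fraction(subgroups, population_lifetime_risk)
  point_exact <- annual_cases * cf * reduction
  out <- tibble::tibble(
    case_fraction = cf,
    prevented_point = round_half_away(point_exact),
    prevented_low = round_half_away(annual_cases * cf * reduction_low),
    prevented_high = round_half_away(annual_cases * cf * reduction_high),
    prevented_fraction = point_exact / annual_cases
  )
  class(out) <- c("bc_impact", class(out))
  out
}

#' @export
print.bc_impact <- function(x, ...) {
  cat(sprintf(
    paste0("<bc_impact> case fraction %.2f%% | prevented %d ",
           "(range %d-%d) | %.1f%% of annual cases\n"),
    100 * x$case_fraction, x$prevented_point, x$prevented_low,
    x$prevented_high, 100 * x$prevented_fraction))
  invisible(x)
}

#' Population-impact report for a parameter bundle
#'
#' Convenience wrapper applying [prevented_cases()] to the impact block of a
#' parameter bundle.
#'
#' @param bundle Parameter bundle (see [generate_fixture()]).
#' @return A `bc_impact` row.
#' @export
impact_report <- function(bundle) {
  im <- bundle$impact
  prevented_cases(im$subgroups, im$population_lifetime_risk, im$annual_cases,
                  im$rrm_reduction, im$rrm_reduction_low,
                  im$rrm_reduction_high)
}
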