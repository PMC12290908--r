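#' Risk-tiered screening schedule
#'
#' Enumerates the screening events a woman receives under the UK risk-tiered
#' programme, by lifetime breast-cancer risk:
#' * `< 17%` (`SUB_NICE`): routine triennial mammography 50, 53, ..., 68;
#' * `[17%, 32%)` (`TIER_17_32`): annual mammography 40--49, then triennial
#'   50, 53, ..., 68;
#' * `[32%, 45%)` (`TIER_32_45`): annual mammography 40--59, then triennial
#'   60, 63, 66, 69;
#' * `>= 45%` (`TIER_45_PLUS`): annual MRI 30--49 plus annual mammography
#'   50--69.
#'
#' Triennial runs step by 3 from the first eligible age while `<= 69`; no
#' event is ever generated outside ages 30--69.
#'
#' @param lifetime_risk Lifetime risk in (0, 1).
#' @return Object of class `bc_schedule`: list with `tier` (character) and
#'   `events`, a tibble with columns `age` and `modality`
#'   (`"mammography"`/`"mri"`) sorted by age.
#' @examples
#' screening_schedule(0.25)$tier
#' nrow(screening_schedule(0.50)$events)  # 40
#' @export
screening_schedule <- function(lifetime_risk) {
  check_probability(lifetime_risk, "lifetime_risk",
                    allow_zero = FALSE, allow_one = FALSE)
  key <- sprintf("%.12g", lifetime_risk)
  cached <- .schedule_cache[[key]]
  if (!is.null(cached)) return(cached)
  ev <- function(age, modality) tibble::tibble(age = as.integer(age),
                                              modality = modality)
  triennial <- function(from) seq.int(from, 69L, by = 3L)
  if (lifetime_risk < 0.17) {
    tier <- "SUB_NICE"
    events <- ev(triennial(50L), "mammography")
  } else if (lifetime_risk < 0.32) {
    tier <- "TIER_17_32"
    events <- dplyr::bind_rows(ev(40:49, "mammography"),
                               ev(triennial(50L), "mammography"))
  } else if (lifetime_risk < 0.45) {
    tier <- "TIER_32_45"
    events <- dplyr::bind_rows(ev(40:59, "mammography"),
                               ev(triennial(60L), "mammography"))
  } else {
    tier <- "TIER_45_PLUS"
    events <- dplyr::bind_rows(ev(30:49, "mri"),
                               ev(50:69, "mammography"))
  }
  events <- dplyr::arrange(events, .data$age, .data$modality)
  stopifnot(!anyDuplicated(events[c("age", "modality")]),
            all(events$age >= 30L & events$age <= 69L))
  out <- structure(list(tier = tier, events = events), class = "bc_schedule")
  .schedule_cache[[key]] <- out
  out
}

# schedules depend on risk alone; memoized because the PSA rebuilds
# strategies thousands of times
.schedule_cache <- new.env(parent = emptyenv())

#' Medical-prevention plan by lifetime risk
#'
#' Five years of tamoxifen (premenopausal) or anastrozole (postmenopausal)
#' with 16.3% uptake. Women at 30%+ lifetime risk start at age 30; women at
#' 17%--30% start at 40; below 17% no plan is offered (`NULL`).
#'
#' @param lifetime_risk Lifetime risk in (0, 1).
#' @param uptake Proportion accepting prevention (default 0.163).
#' @param hr_tamoxifen,hr_anastrozole Incidence hazard ratios while treated,
#'   in (0, 1\].
#' @param duration Treatment years (default 5).
#' @param carryover Additional years the risk reduction persists after
#'   treatment stops (default 5).
#' @return Object of class `bc_prevention` (a list of the fields above plus
#'   `start_age`), or `NULL` when `lifetime_risk < 0.17`.
#' @export
prevention_plan <- function(lifetime_risk, uptake = 0.163,
                            hr_tamoxifen = 0.71, hr_anastrozole = 0.51,
                            duration = 5, carryover = 5) {
  check_probability(lifetime_risk, "lifetime_risk",
                    allow_zero = FALSE, allow_one = FALSE)
  if (lifetime_risk < 0.17) return(NULL)
  check_probability(uptake, "uptake")
  check_probability(c(hr_tamoxifen, hr_anastrozole), "prevention hazard ratio",
                    allow_zero = FALSE)
  if (duration <= 0) abort_rrmcea("duration must be positive",
                                  "rrmcea_domain_error")
  structure(
    list(start_age = if (lifetime_risk >= 0.30) 30L else 40L,
         duration = as.integer(duration),
         uptake = uptake,
         hr_tamoxifen = hr_tamoxifen,
         hr_anastrozole = hr_anastrozole,
         carryover_years = as.integer(carryover)),
    class = "bc_prevention"
  )
}

#' Construct the two comparator strategies
#'
#' Builds the RRM arm (surgery at the cohort start age, residual incidence
#' multiplier `rrm_hazard_ratio`) and the screening arm (risk-tiered schedule
#' plus medical prevention) for one risk profile. Both arms assume 100%
#' uptake of surgery/screening.
#'
#' @param profile A [risk_profile()].
#' @param start_age Cohort start / surgery age, in \[30, 60\].
#' @param rrm_hazard_ratio Residual incidence multiplier after surgery
#'   (default 0.09, i.e. ~91% risk reduction).
#' @param prevention_args Named list of overrides passed to
#'   [prevention_plan()].
#' @return Named list with elements `rrm` and `screen`, each of class
#'   `bc_strategy` with fields `kind` (`"RRM"`/`"SCREEN"`), `rrm_age`,
#'   `rrm_hazard_ratio`, `schedule`, `prevention`.
#' @export
make_strategies <- function(profile, start_age, rrm_hazard_ratio = 0.09,
                            prevention_args = list()) {
  if (start_age < 30 || start_age > 60) {
    abort_rrmcea("start_age must lie in [30, 60]", "rrmcea_range_error")
  }
  risk <- profile$lifetime_risk_target
  rrm <- structure(
    list(kind = "RRM", rrm_age = as.integer(start_age),
         rrm_hazard_ratio = rrm_hazard_ratio,
         schedule = NULL, prevention = NULL),
    class = "bc_strategy"
  )
  screen <- structure(
    list(kind = "SCREEN", rrm_age = NULL, rrm_hazard_ratio = NULL,
         schedule = screening_schedule(risk),
         prevention = do.call(prevention_plan,
                              c(list(lifetime_risk = risk), prevention_args))),
    class = "bc_strategy"
  )
  list(rrm = rrm, screen = screen)
}

#' Screening schedule as a tibble
#'
#' @param x A `bc_schedule`.
#' @param ... Unused.
#' @return Tibble with `age`, `modality`, `tier`.
#' @method as_tibble bc_schedule
#' @export
as_tibble.bc_schedule <- function(x, ...) {
  dplyr::mutate(x$events, tier = x$tier)
}

#' @export
print.bc_schedule <- function(x, ...) {
  counts <- table(x$events$modality)
  cat(sprintf("<bc_schedule> tier %s | %s\n", x$tier,
              paste(sprintf("%s x%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' @export
print.bc_strategy <- function(x, ...) {
  if (x$kind == "RRM") {
    cat(sprintf("<bc_strategy> RRM at age %d (residual HR %.2f)\n",
                x$rrm_age, x$rrm_hazard_ratio))
  } else {
    cat(sprintf("<bc_strategy> screening %s%s\n", x$schedule$tier,
                if (is.null(x$prevention)) "" else
                  sprintf(" + prevention from %d", x$prevention$start_age)))
  }
  invisible(x)
}

# active screening age window [lo, hi] implied by a schedule (for the
# stage-distribution context); NULL when there is no schedule
screening_window <- function(schedule) {
  if (is.null(schedule) || nrow(schedule$events) == 0) return(NULL)
  c(min(schedule$events$age), 69L)
}
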