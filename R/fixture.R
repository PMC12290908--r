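# Derive a 5 x 20 annual BC-death probability matrix from 20-year survival,
# one constant annual hazard per stage.
death_matrix_from_survival <- function(surv20) {
  q <- 1 - surv20^(1 / 20)
  matrix(rep(q, 20), nrow = 5, ncol = 20,
         dimnames = list(stage = bc_stages(), ysd = 1:20))
}

recurrence_matrix <- function(annual, active_years = 10) {
  m <- matrix(0, 5, 20, dimnames = list(stage = bc_stages(), ysd = 1:20))
  m[, seq_len(active_years)] <- annual
  m
}

#' Generate a synthetic parameter bundle
#'
#' Builds a complete, validated parameter bundle containing everything the
#' model needs. Two flavours:
#'
#' * `"paper_like"`: the curated fixture. Embeds the headline reference
#'   values — baseline lifetime risk 10.79% over ages 20--80 (a
#'   log-quadratic incidence shape peaking at 65, calibrated by
#'   [calibrate_baseline()] against a Gompertz approximation of UK female
#'   all-cause mortality), prevention uptake 16.3%, discounting 3.5%,
#'   residual RRM hazard ratio 0.09 with range 0.02--0.38 (complements of a
#'   62%--98% risk reduction), WTP pair 20 000 / 30 000 per QALY, horizon 80,
#'   20-year survivor cutoff, 1/52- and 5/52-year event disutilities, and the
#'   published prevalence mix for the population-impact arithmetic. The
#'   remaining inputs (stage survival, recurrence, unit costs, state
#'   utilities) are plausible, documented, synthetic defaults.
#' * `"random_valid"`: the paper-like bundle jittered within plausible
#'   ranges under `seed`, for property tests. Screening-tier costs and a
#'   flat RRM cost are preserved so ICER stays monotone in risk by
#'   construction.
#'
#' Deterministic: the same `(seed, realism, overrides)` always returns an
#' identical bundle.
#'
#' @param seed Integer seed (used by `"random_valid"`; recorded either way).
#' @param realism `"paper_like"` or `"random_valid"`.
#' @param overrides Named list of dot-path overrides applied before
#'   validation, e.g. `list("costs.rrm" = 9000)`. An override that breaks an
#'   invariant errors with the violated rule.
#' @return A validated bundle of class `bc_params`: a list with blocks
#'   `meta`, `config`, `risk`, `tables` (incidence / mortality /
#'   utility-norm rate tables), `strategy`, `disease`, `costs`, `utilities`,
#'   `impact`, `wtp`.
#' @export
generate_fixture <- function(seed = 1L, realism = c("paper_like",
                                                    "random_valid"),
                             overrides = list()) {
  realism <- match.arg(realism)
  ages <- 20:79

  # documented synthetic constants (see the methods vignette)
  mortality <- age_rate_table(ages, exp(-11.6 + 0.1 * ages))
  shape <- age_rate_table(ages, 0.004 * exp(-((ages - 65)^2) / (2 * 18^2)))
  incidence <- calibrate_baseline(shape, mortality, 0.1079)
  attr(incidence, "multiplier") <- NULL
  norms <- age_rate_table(ages, 0.95 - 0.0035 * (ages - 20))

  surv_scr <- c(dcis = 0.98, stage1 = 0.92, stage2 = 0.78,
                stage3 = 0.52, stage4 = 0.10)
  surv_gen <- c(dcis = 0.97, stage1 = 0.89, stage2 = 0.72,
                stage3 = 0.45, stage4 = 0.07)
  surv_rrm <- c(dcis = 0.985, stage1 = 0.93, stage2 = 0.80,
                stage3 = 0.55, stage4 = 0.12)
  rec_dist <- c(dcis = 0.001, stage1 = 0.005, stage2 = 0.015,
                stage3 = 0.030, stage4 = 0)
  rec_loc <- rec_dist / 2

  pathology_screened <- c(er_pos = 0.85, erbb2_pos = 0.12,
                          node_pos = 0.25, premenopausal = 0.55)
  pathology_general <- c(er_pos = 0.80, erbb2_pos = 0.15,
                         node_pos = 0.35, premenopausal = 0.25)

  # first-year treatment costs built as an ER-status convex combination plus
  # expected ERBB2 / node uplifts, exercising weight_treatment_costs()
  base_first <- c(dcis = 7000, stage1 = 11000, stage2 = 16000,
                  stage3 = 23000, stage4 = 28000)
  er_extra <- 800; erbb2_extra <- c(0, 12000, 15000, 18000, 18000)
  node_extra <- c(0, 2500, 3000, 3500, 0)
  subtype_costs <- tibble::tibble(
    stage = bc_stages(),
    er_positive = base_first + er_extra,
    er_negative = base_first
  )
  mix <- c(er_positive = unname(pathology_screened["er_pos"]),
           er_negative = 1 - unname(pathology_screened["er_pos"]))
  first_year <- weight_treatment_costs(subtype_costs, mix)$cost +
    pathology_screened["erbb2_pos"] * erbb2_extra +
    pathology_screened["node_pos"] * node_extra
  treatment <- tibble::tibble(
    stage = bc_stages(),
    first_year = as.numeric(first_year),
    subsequent_year = c(400, 700, 1100, 2000, 7500),
    terminal = c(6000, 7000, 8000, 9000, 10000)
  )

  bundle <- list(
    meta = list(schema_version = "1.0", realism = realism,
                seed = as.integer(seed)),
    config = list(start_age = 30L, horizon_age = 80L, menopause_age = 51L,
                  discount_rate_costs = 0.035, discount_rate_effects = 0.035),
    risk = list(baseline_lifetime_risk = 0.1079),
    tables = list(incidence = incidence, mortality = mortality,
                  utility_norms = norms),
    strategy = list(
      rrm_hazard_ratio = 0.09,
      rrm_hazard_ratio_low = 0.02, rrm_hazard_ratio_high = 0.38,
      prevention_uptake = 0.163,
      hr_tamoxifen = 0.71, hr_anastrozole = 0.51,
      prevention_duration = 5L, prevention_carryover = 5L,
      fp_rate_mammography = 0.03, fp_rate_mri = 0.07
    ),
    disease = list(
      stage_dist_screened = c(dcis = 0.25, stage1 = 0.40, stage2 = 0.25,
                              stage3 = 0.08, stage4 = 0.02),
      stage_dist_general = c(dcis = 0.10, stage1 = 0.35, stage2 = 0.35,
                             stage3 = 0.15, stage4 = 0.05),
      bc_death_screened = death_matrix_from_survival(surv_scr),
      bc_death_general = death_matrix_from_survival(surv_gen),
      bc_death_post_rrm = death_matrix_from_survival(surv_rrm),
      recurrence_local = recurrence_matrix(rec_loc),
      recurrence_distant = recurrence_matrix(rec_dist),
      recurrence_local_post_rrm = recurrence_matrix(rec_loc * 0.9),
      recurrence_distant_post_rrm = recurrence_matrix(rec_dist * 0.9),
      distant_death_annual = 0.25,
      pathology_screened = pathology_screened,
      pathology_general = pathology_general,
      survivor_cutoff = 20L
    ),
    costs = list(
      rrm = 8000, mammography = 50, mri = 300,
      fp_recall = 150, fp_biopsy = 400, fp_biopsy_fraction = 0.2,
      tamoxifen_annual = 35, anastrozole_annual = 45,
      distant_recurrence_annual = 7500,
      local_recurrence_event = 5000,
      treatment = treatment
    ),
    utilities = list(
      norms = norms,
      state = tibble::tibble(
        stage = bc_stages(),
        first_year = c(0.92, 0.85, 0.80, 0.75, 0.60),
        subsequent = c(0.96, 0.92, 0.88, 0.82, 0.65)
      ),
      distant_recurrence = 0.60,
      survivor = 0.95,
      decrements = list(rrm = 0.05, screening = 0.10,
                        false_positive = 0.10, prevention = 0.03)
    ),
    impact = list(
      population_lifetime_risk = 0.11,
      annual_cases = 58756L,
      rrm_reduction = 0.91, rrm_reduction_low = 0.62,
      rrm_reduction_high = 0.98,
      subgroups = tibble::tibble(
        name = c("brca1_brca2", "other_high_risk"),
        prevalence = c(0.005, 0.025),
        mean_lifetime_risk = c(0.60, 0.418)
      )
    ),
    wtp = list(low = 20000, high = 30000)
  )

  if (realism == "random_valid") {
    set.seed(seed)
    jit <- function(x, f = 0.2) x * stats::runif(length(x), 1 - f, 1 + f)
    jp <- function(x, f = 0.2) pmin(jit(x, f), 0.99)  # keep probabilities < 1
    b <- bundle
    b$costs$rrm <- jit(b$costs$rrm)
    b$costs$mammography <- jit(b$costs$mammography)
    b$costs$mri <- jit(b$costs$mri)
    b$costs$treatment$first_year <- jit(b$costs$treatment$first_year)
    b$costs$treatment$subsequent_year <- jit(b$costs$treatment$subsequent_year)
    b$costs$treatment$terminal <- jit(b$costs$treatment$terminal)
    b$strategy$rrm_hazard_ratio <- jp(b$strategy$rrm_hazard_ratio)
    b$strategy$prevention_uptake <- jp(b$strategy$prevention_uptake)
    b$strategy$hr_tamoxifen <- jp(b$strategy$hr_tamoxifen, 0.1)
    b$strategy$hr_anastrozole <- jp(b$strategy$hr_anastrozole, 0.1)
    b$strategy$fp_rate_mammography <- jp(b$strategy$fp_rate_mammography)
    b$strategy$fp_rate_mri <- jp(b$strategy$fp_rate_mri)
    b$disease$distant_death_annual <- jp(b$disease$distant_death_annual, 0.1)
    for (nm in c("bc_death_screened", "bc_death_general",
                 "bc_death_post_rrm", "recurrence_local",
                 "recurrence_distant", "recurrence_local_post_rrm",
                 "recurrence_distant_post_rrm")) {
      b$disease[[nm]] <- pmin(b$disease[[nm]] *
                                stats::runif(1, 0.8, 1.2), 0.99)
    }
    for (nm in c("stage_dist_screened", "stage_dist_general")) {
      p <- b$disease[[nm]] * stats::runif(5, 0.8, 1.2)
      b$disease[[nm]] <- p / sum(p)
    }
    u <- b$utilities
    u$state$first_year <- pmin(jit(u$state$first_year, 0.05), 1)
    u$state$subsequent <- pmin(pmax(u$state$subsequent,
                                    u$state$first_year), 1)
    u$distant_recurrence <- jp(u$distant_recurrence, 0.05)
    u$survivor <- jp(u$survivor, 0.03)
    b$utilities <- u
    bundle <- b
  }

  for (nm in names(overrides)) {
    bundle <- bundle_set(bundle, nm, overrides[[nm]])
  }
  class(bundle) <- "bc_params"
  report <- validate_params(bundle)
  if (nrow(report) > 0) {
    abort_rrmcea(paste0("fixture fails validation:\n",
                        paste(report$path, report$message, sep = ": ",
                              collapse = "\n")),
                 "rrmcea_validation_error")
  }
  bundle
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant the model relies on and returns a report
#' of violations (empty tibble = valid). Never throws on content, only on an
#' unreadable structure.
#'
#' @param bundle A parameter bundle.
#' @return Tibble with columns `path` and `message`, one row per violation.
#' @export
validate_params <- function(bundle) {
  bad <- list()
  note <- function(path, message) {
    bad[[length(bad) + 1]] <<- tibble::tibble(path = path, message = message)
  }
  prob_ok <- function(x) all(is.finite(x) & x >= 0 & x <= 1)

  for (nm in c("incidence", "mortality", "utility_norms")) {
    tbl <- bundle$tables[[nm]]
    res <- tryCatch({validate_age_rate_table(tbl, nm); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) note(paste0("tables.", nm), res)
    else if (min(tbl$age) > 20 || max(tbl$age) < 79) {
      note(paste0("tables.", nm), "must cover ages 20-79")
    }
  }
  cfg <- bundle$config
  if (!(cfg$start_age >= 30 && cfg$start_age <= 60 &&
        cfg$start_age < cfg$horizon_age && cfg$horizon_age <= 80)) {
    note("config", "need 30 <= start_age <= 60 < horizon_age <= 80")
  }
  if (cfg$discount_rate_costs < 0 || cfg$discount_rate_effects < 0) {
    note("config", "discount rates must be >= 0")
  }
  st <- bundle$strategy
  if (!prob_ok(st$rrm_hazard_ratio)) {
    note("strategy.rrm_hazard_ratio", "must be a probability in [0, 1]")
  }
  if (!prob_ok(st$prevention_uptake)) {
    note("strategy.prevention_uptake", "uptake must lie in [0, 1]")
  }
  if (!prob_ok(c(st$hr_tamoxifen, st$hr_anastrozole)) ||
      any(c(st$hr_tamoxifen, st$hr_anastrozole) == 0)) {
    note("strategy", "prevention hazard ratios must lie in (0, 1]")
  }
  if (!prob_ok(c(st$fp_rate_mammography, st$fp_rate_mri))) {
    note("strategy", "false-positive rates must lie in [0, 1]")
  }
  dz <- bundle$disease
  for (nm in c("stage_dist_screened", "stage_dist_general")) {
    p <- dz[[nm]]
    if (length(p) != 5 || !prob_ok(p) || abs(sum(p) - 1) > 1e-9) {
      note(paste0("disease.", nm),
           "stage distribution must be 5 probabilities summing to 1")
    }
  }
  for (nm in c("bc_death_screened", "bc_death_general", "bc_death_post_rrm",
               "recurrence_local", "recurrence_distant",
               "recurrence_local_post_rrm", "recurrence_distant_post_rrm")) {
    m <- dz[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(5, 20)) || !prob_ok(m)) {
      note(paste0("disease.", nm), "must be a 5x20 probability matrix")
    }
  }
  exit_scr <- dz$bc_death_screened + dz$recurrence_distant
  exit_gen <- dz$bc_death_general + dz$recurrence_distant
  if (any(exit_scr > 1) || any(exit_gen > 1)) {
    note("disease", "per-cycle stage exit probabilities must sum to <= 1")
  }
  if (!prob_ok(dz$distant_death_annual)) {
    note("disease.distant_death_annual", "must lie in [0, 1]")
  }
  if (!identical(dz$survivor_cutoff, 20L)) {
    note("disease.survivor_cutoff", "survivor cutoff is fixed at 20 years")
  }
  cs <- bundle$costs
  scalars <- c(cs$rrm, cs$mammography, cs$mri, cs$fp_recall, cs$fp_biopsy,
               cs$tamoxifen_annual, cs$anastrozole_annual,
               cs$distant_recurrence_annual, cs$local_recurrence_event,
               cs$treatment$first_year, cs$treatment$subsequent_year,
               cs$treatment$terminal)
  if (any(!is.finite(scalars)) || any(scalars < 0)) {
    note("costs", "all costs must be non-negative")
  }
  if (!prob_ok(cs$fp_biopsy_fraction)) {
    note("costs.fp_biopsy_fraction", "must lie in [0, 1]")
  }
  ut <- bundle$utilities
  if (!prob_ok(c(ut$state$first_year, ut$state$subsequent,
                 ut$distant_recurrence, ut$survivor))) {
    note("utilities", "state utilities must lie in [0, 1]")
  }
  dec <- unlist(ut$decrements)
  if (any(!is.finite(dec)) || any(dec < 0)) {
    note("utilities.decrements", "decrements must be >= 0")
  }
  im <- bundle$impact
  if (sum(im$subgroups$prevalence) > 1 ||
      !prob_ok(im$subgroups$prevalence) ||
      !prob_ok(im$subgroups$mean_lifetime_risk)) {
    note("impact.subgroups", "prevalences/risks must be valid proportions")
  }
  if (!(im$rrm_reduction_low <= im$rrm_reduction &&
        im$rrm_reduction <= im$rrm_reduction_high) ||
      !prob_ok(c(im$rrm_reduction_low, im$rrm_reduction,
                 im$rrm_reduction_high))) {
    note("impact", "need reduction low <= point <= high, all in [0, 1]")
  }
  if (length(bad) == 0) {
    tibble::tibble(path = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Default probabilistic / one-way sensitivity parameter specs
#'
#' One row per varied scalar: costs get a gamma distribution and a +/-30%
#' deterministic range; probabilities a beta distribution and +/-10%;
#' utilities and decrements a lognormal and +/-10%. The RRM residual hazard
#' ratio uses its published range (0.02--0.38). Default dispersion is
#' `se = 10%` of the point value.
#'
#' @param bundle Parameter bundle.
#' @return Tibble with columns `name`, `point`, `low`, `high`,
#'   `distribution`, `se`.
#' @export
default_param_specs <- function(bundle) {
  row <- function(name, dist, low = NULL, high = NULL) {
    point <- bundle_get(bundle, name)
    f <- if (dist == "GAMMA") 0.30 else 0.10
    tibble::tibble(
      name = name, point = point,
      low = if (is.null(low)) point * (1 - f) else low,
      high = if (is.null(high)) pmin(point * (1 + f),
                                     if (dist == "GAMMA") Inf else 1)
             else high,
      distribution = dist, se = 0.1 * point)
  }
  dplyr::bind_rows(
    row("strategy.rrm_hazard_ratio", "BETA",
        low = bundle$strategy$rrm_hazard_ratio_low,
        high = bundle$strategy$rrm_hazard_ratio_high),
    row("strategy.prevention_uptake", "BETA"),
    row("strategy.hr_tamoxifen", "BETA"),
    row("strategy.hr_anastrozole", "BETA"),
    row("strategy.fp_rate_mammography", "BETA"),
    row("strategy.fp_rate_mri", "BETA"),
    row("disease.distant_death_annual", "BETA"),
    row("costs.rrm", "GAMMA"),
    row("costs.mammography", "GAMMA"),
    row("costs.mri", "GAMMA"),
    row("costs.fp_recall", "GAMMA"),
    row("costs.fp_biopsy", "GAMMA"),
    row("costs.tamoxifen_annual", "GAMMA"),
    row("costs.anastrozole_annual", "GAMMA"),
    row("costs.distant_recurrence_annual", "GAMMA"),
    row("costs.local_recurrence_event", "GAMMA"),
    row("costs.treatment.first_year.stage1", "GAMMA"),
    row("costs.treatment.first_year.stage2", "GAMMA"),
    row("costs.treatment.subsequent_year.stage4", "GAMMA"),
    row("utilities.distant_recurrence", "LOGNORMAL"),
    row("utilities.survivor", "LOGNORMAL"),
    row("utilities.state.first_year.stage1", "LOGNORMAL"),
    row("utilities.state.subsequent.stage1", "LOGNORMAL"),
    row("utilities.decrements.rrm", "LOGNORMAL"),
    row("utilities.decrements.screening", "LOGNORMAL"),
    row("utilities.decrements.false_positive", "LOGNORMAL"),
    row("utilities.decrements.prevention", "LOGNORMAL"),
    row("config.discount_rate_costs", "FIXED",
        low = 0.015, high = 0.06),
    row("config.discount_rate_effects", "FIXED",
        low = 0.015, high = 0.06)
  )
}

#' @export
print.bc_params <- function(x, ...) {
  cat(sprintf("<bc_params> %s fixture (seed %d), schema %s\n",
              x$meta$realism, x$meta$seed, x$meta$schema_version))
  invisible(x)
}
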