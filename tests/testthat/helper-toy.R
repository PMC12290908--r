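# Small builders shared across tests.

const_table <- function(ages, v) age_rate_table(ages, rep(v, length(ages)))

# a risk profile wrapping a given incidence table directly (hazard ratio 1)
toy_profile <- function(incidence, target = 0.2) {
  structure(list(lifetime_risk_target = target,
                 baseline_lifetime_risk = target,
                 hazard_ratio = 1,
                 scaled_incidence = incidence),
            class = "bc_risk_profile")
}

# a SCREEN-arm strategy with no prevention and a given (or sub-NICE) schedule
toy_screen_strategy <- function(schedule = screening_schedule(0.16)) {
  structure(list(kind = "SCREEN", rrm_age = NULL, rrm_hazard_ratio = NULL,
                 schedule = schedule, prevention = NULL),
            class = "bc_strategy")
}

toy_rrm_strategy <- function(rrm_age, hr = 0.09) {
  structure(list(kind = "RRM", rrm_age = as.integer(rrm_age),
                 rrm_hazard_ratio = hr, schedule = NULL, prevention = NULL),
            class = "bc_strategy")
}

stage_mat <- function(x) {
  if (length(x) == 1) x <- rep(x, 5)
  matrix(rep(x, 20), nrow = 5, ncol = 20,
         dimnames = list(stage = c("dcis", "stage1", "stage2", "stage3",
                                   "stage4"), ysd = 1:20))
}

# full disease-history parameter list for direct run_cohort() calls; screened
# and general contexts identical unless overridden
toy_disease <- function(stage_dist = c(dcis = 0, stage1 = 1, stage2 = 0,
                                       stage3 = 0, stage4 = 0),
                        q = stage_mat(0), rd = stage_mat(0),
                        rl = stage_mat(0), qd = 0,
                        stage_dist_screened = stage_dist,
                        fp_mam = 0, fp_mri = 0) {
  list(stage_dist_screened = stage_dist_screened,
       stage_dist_general = stage_dist,
       bc_death_screened = q, bc_death_general = q, bc_death_post_rrm = q,
       recurrence_local = rl, recurrence_distant = rd,
       recurrence_local_post_rrm = rl, recurrence_distant_post_rrm = rd,
       distant_death_annual = qd,
       survivor_cutoff = 20L,
       fp_rate_mammography = fp_mam, fp_rate_mri = fp_mri)
}

# disease params of a generated bundle, augmented with its fp rates, for
# direct run_cohort() calls
disease_params <- function(bundle) {
  c(bundle$disease,
    list(fp_rate_mammography = bundle$strategy$fp_rate_mammography,
         fp_rate_mri = bundle$strategy$fp_rate_mri))
}

run_bundle_arm <- function(bundle, lifetime_risk, start_age,
                           arm = c("screen", "rrm")) {
  arm <- match.arg(arm)
  profile <- risk_profile(bundle$tables$incidence, lifetime_risk,
                          bundle$risk$baseline_lifetime_risk)
  config <- model_config(start_age, bundle$config$horizon_age,
                         bundle$config$menopause_age)
  strat <- make_strategies(profile, start_age,
                           rrm_hazard_ratio = bundle$strategy$rrm_hazard_ratio)
  run_cohort(strat[[arm]], profile, disease_params(bundle), config,
             bundle$tables$mortality)
}
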