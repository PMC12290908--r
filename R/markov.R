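#' Model configuration
#'
#' @param start_age Cohort entry (and RRM surgery) age, years, in \[30, 60\].
#' @param horizon_age End of follow-up (exclusive upper age), default 80.
#' @param menopause_age Age at which prevention switches from tamoxifen to
#'   anastrozole, default 51.
#' @return Object of class `bc_config`.
#' @export
model_config <- function(start_age, horizon_age = 80, menopause_age = 51) {
  if (!(start_age >= 30 && start_age <= 60 && start_age < horizon_age &&
        horizon_age <= 80)) {
    abort_rrmcea("need 30 <= start_age <= 60 < horizon_age <= 80",
                 "rrmcea_range_error")
  }
  structure(list(start_age = as.integer(start_age),
                 horizon_age = as.integer(horizon_age),
                 cycle_length = 1L,
                 menopause_age = as.integer(menopause_age)),
            class = "bc_config")
}

#' Stage distribution at diagnosis for a given age
#'
#' Women diagnosed while inside the active screening age window receive the
#' screened-context stage distribution (earlier-stage shifted); women
#' diagnosed outside it (or on an arm with no screening schedule) receive the
#' general-population distribution.
#'
#' @param age Age at diagnosis, years.
#' @param schedule A `bc_schedule` or `NULL` (no screening).
#' @param params Disease-history parameter list holding
#'   `stage_dist_screened` and `stage_dist_general` (named vectors over the
#'   five diagnosis stages, each summing to 1).
#' @return Named numeric vector of probabilities over
#'   `dcis, stage1, ..., stage4`.
#' @export
stage_distribution_at <- function(age, schedule, params) {
  check_stage_distribution(params$stage_dist_screened, "stage_dist_screened")
  check_stage_distribution(params$stage_dist_general, "stage_dist_general")
  win <- screening_window(schedule)
  if (!is.null(win) && age >= win[1] && age <= win[2]) {
    params$stage_dist_screened
  } else {
    params$stage_dist_general
  }
}

check_stage_distribution <- function(p, what) {
  if (is.null(p) || length(p) != 5 || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    abort_rrmcea(sprintf("%s must be 5 non-negative probabilities summing to 1",
                         what),
                 "rrmcea_validation_error")
  }
  invisible(p)
}

#' Apply strategy effects to age-specific incidence
#'
#' RRM arm: incidence multiplied by the residual hazard ratio from the
#' surgery age onward. Screening arm: during the prevention window (treatment
#' years plus carryover) incidence is multiplied by
#' `(1 - uptake) + uptake * HR(agent)`, the agent being tamoxifen below the
#' menopause age and anastrozole at or above it.
#'
#' @param incidence Rate table (typically `profile$scaled_incidence`).
#' @param strategy A `bc_strategy`.
#' @param config A [model_config()].
#' @return Modified rate table.
#' @export
apply_strategy_modifiers <- function(incidence, strategy, config) {
  tbl <- validate_age_rate_table(incidence, "incidence")
  if (strategy$kind == "RRM") {
    hr <- strategy$rrm_hazard_ratio
    check_probability(hr, "rrm_hazard_ratio")
    idx <- tbl$age >= strategy$rrm_age
    tbl$value[idx] <- tbl$value[idx] * hr
  } else if (!is.null(strategy$prevention)) {
    pv <- strategy$prevention
    win_end <- pv$start_age + pv$duration + pv$carryover_years
    idx <- tbl$age >= pv$start_age & tbl$age < win_end
    agent_hr <- ifelse(tbl$age[idx] < config$menopause_age,
                       pv$hr_tamoxifen, pv$hr_anastrozole)
    tbl$value[idx] <- tbl$value[idx] * ((1 - pv$uptake) + pv$uptake * agent_hr)
  }
  tbl
}

state_names <- function() {
  c("healthy",
    as.vector(outer(bc_stages(), 1:20, function(s, y) paste0(s, "_y", y))),
    "distant_recurrence", "long_term_survivor", "dead_bc", "dead_other")
}

# columns of the tunnel block inside the state vector, as a 5 x 20 index
tunnel_index <- function() matrix(seq_len(100) + 1L, nrow = 5, ncol = 20)

#' Run the annual-cycle Markov cohort
#'
#' Deterministic propagation of a unit cohort from `start_age` to the horizon
#' over the states: healthy; five diagnosis stages (DCIS, stages 1--4), each a
#' 20-year years-since-diagnosis tunnel; distant recurrence; long-term
#' survivor; breast-cancer death; other-cause death.
#'
#' Within a cycle at age `a`: healthy women are first exposed to the
#' (strategy-modified) diagnosis probability — new diagnoses split across
#' stages by [stage_distribution_at()] and enter tunnel year 1 the next cycle
#' — and the non-diagnosed then face other-cause death. Tunnel occupants face
#' other-cause death, then stage- and year-specific breast-cancer death, then
#' distant recurrence (moving to the distant-recurrence state) and local
#' recurrence (an event flow; the woman stays in her tunnel). Women alive and
#' distant-recurrence-free 20 years after diagnosis become long-term
#' survivors, subject only to general-population mortality. Because a tunnel
#' cell at years-since-diagnosis `j` in cycle `k` was diagnosed at age
#' `a - j`, the screened vs general parameter context is resolved per cell
#' from the diagnosis age.
#'
#' Probability mass is checked every cycle; a leak beyond 1e-9 aborts.
#'
#' @param strategy A `bc_strategy` (from [make_strategies()]).
#' @param profile A [risk_profile()].
#' @param params Disease-history parameter list (`bundle$disease`): stage
#'   distributions, annual BC-death matrices (`bc_death_screened`,
#'   `bc_death_general`, `bc_death_post_rrm`; 5 stages x 20 years),
#'   recurrence matrices (`recurrence_local`, `recurrence_distant` and
#'   `_post_rrm` variants), `distant_death_annual`, false-positive rates
#'   `fp_rate_mammography` / `fp_rate_mri`.
#' @param config A [model_config()].
#' @param mortality Rate table of annual all-cause mortality.
#' @return Object of class `bc_trace`: list with `states` (matrix, one row
#'   per cycle 0..H, one column per state), `flows` (tibble, one row per
#'   cycle 0..H-1 of event counts), `config`, `strategy_kind`.
#' @export
run_cohort <- function(strategy, profile, params, config, mortality) {
  mort <- validate_age_rate_table(mortality, "mortality")
  inc_tbl <- apply_strategy_modifiers(profile$scaled_incidence, strategy,
                                      config)
  H <- config$horizon_age - config$start_age
  ages <- config$start_age + 0:(H - 1)
  inc <- rate_window(inc_tbl, config$start_age, config$horizon_age,
                     "incidence")
  m <- rate_window(mort, config$start_age, config$horizon_age, "mortality")

  post_rrm <- strategy$kind == "RRM"
  win <- if (post_rrm) NULL else screening_window(strategy$schedule)
  sched <- if (post_rrm || is.null(strategy$schedule)) {
    tibble::tibble(age = integer(), modality = character())
  } else {
    dplyr::filter(strategy$schedule$events, .data$age >= config$start_age)
  }
  pv <- if (post_rrm) NULL else strategy$prevention

  # precompute per-cycle screen counts and diagnosis-stage distributions
  # (at most one event per age and modality, by schedule invariant)
  n_mam <- as.integer(ages %in% sched$age[sched$modality == "mammography"])
  n_mri <- as.integer(ages %in% sched$age[sched$modality == "mri"])
  check_stage_distribution(params$stage_dist_screened, "stage_dist_screened")
  check_stage_distribution(params$stage_dist_general, "stage_dist_general")
  in_win <- if (is.null(win)) rep(FALSE, H) else
    ages >= win[1] & ages <= win[2]
  sd_by_cycle <- matrix(params$stage_dist_general, H, 5, byrow = TRUE)
  if (any(in_win)) {
    sd_by_cycle[in_win, ] <- matrix(params$stage_dist_screened,
                                    sum(in_win), 5, byrow = TRUE)
  }

  q_scr <- params$bc_death_screened
  q_gen <- params$bc_death_general
  q_rrm <- params$bc_death_post_rrm
  rl <- params$recurrence_local
  rd <- params$recurrence_distant
  rl_rrm <- params$recurrence_local_post_rrm
  rd_rrm <- params$recurrence_distant_post_rrm
  qd <- params$distant_death_annual

  sn <- state_names()
  n_states <- length(sn)
  ti <- tunnel_index()
  states <- matrix(0, nrow = H + 1, ncol = n_states,
                   dimnames = list(cycle = 0:H, state = sn))
  states[1, "healthy"] <- 1

  fl <- matrix(0, nrow = H, ncol = 17, dimnames = list(NULL, c(
    paste0("diag_", bc_stages()),
    "screens_mammography", "screens_mri", "false_positives",
    paste0("bc_death_", bc_stages()), "bc_death_distant",
    "other_deaths", "prevention_treated_py", "rrm_events")))
  loc_flow <- dist_flow <- numeric(H)

  Tn <- matrix(0, nrow = 5, ncol = 20)  # tunnel occupancy, stages x ysd
  h <- 1; d <- 0; l <- 0; dbc <- 0; doth <- 0

  for (k in seq_len(H)) {
    a <- ages[k]
    # context per tunnel column: diagnosed at age a - j
    if (post_rrm) {
      Q <- q_rrm; RL <- rl_rrm; RD <- rd_rrm
    } else {
      diag_age <- a - (1:20)
      scr <- !is.null(win) & diag_age >= win[1] & diag_age <= win[2]
      Q <- q_gen; RL <- rl; RD <- rd
      if (any(scr)) Q[, scr] <- q_scr[, scr]
    }

    # healthy: diagnosis first, then other-cause death among the non-diagnosed
    diag <- h * inc[k]
    sd_k <- sd_by_cycle[k, ]
    h_dead <- h * (1 - inc[k]) * m[k]
    h_next <- h * (1 - inc[k]) * (1 - m[k])

    # tunnels: other-cause death, BC death, recurrence, then advance
    To <- Tn * (1 - m[k])
    t_dead_other <- sum(Tn) * m[k]
    bc_dead <- To * Q
    rem <- To - bc_dead
    dist <- rem * RD
    loc <- rem * RL
    adv <- rem - dist

    # distant recurrence state
    d_dead_other <- d * m[k]
    d_alive <- d * (1 - m[k])
    d_dead_bc <- d_alive * qd
    d_next <- d_alive * (1 - qd) + sum(dist)

    # long-term survivors
    l_dead_other <- l * m[k]
    l_next <- l * (1 - m[k]) + sum(adv[, 20])

    T_next <- matrix(0, 5, 20)
    T_next[, 2:20] <- adv[, 1:19]
    T_next[, 1] <- diag * sd_k

    dbc_next <- dbc + sum(bc_dead) + d_dead_bc
    doth_next <- doth + h_dead + t_dead_other + d_dead_other + l_dead_other

    # event flows for this cycle
    fp <- h * (n_mam[k] * params$fp_rate_mammography +
                 n_mri[k] * params$fp_rate_mri)
    prev_py <- if (!is.null(pv) &&
                   a >= pv$start_age && a < pv$start_age + pv$duration) {
      h * pv$uptake
    } else 0
    fl[k, ] <- c(diag * sd_k,
                 h * n_mam[k], h * n_mri[k], fp,
                 rowSums(bc_dead), d_dead_bc,
                 h_dead + t_dead_other + d_dead_other + l_dead_other,
                 prev_py,
                 if (post_rrm && k == 1) 1 else 0)
    loc_flow[k] <- sum(loc)
    dist_flow[k] <- sum(dist)

    v <- numeric(n_states)
    v[1] <- h_next
    v[as.vector(ti)] <- as.vector(T_next)
    v[n_states - 3] <- d_next
    v[n_states - 2] <- l_next
    v[n_states - 1] <- dbc_next
    v[n_states] <- doth_next
    leak <- abs(sum(v) - 1)
    if (leak > 1e-9) {
      abort_rrmcea(sprintf("probability mass leak %.3e at cycle %d", leak, k),
                   "rrmcea_consistency_error")
    }
    states[k + 1, ] <- v
    h <- h_next; Tn <- T_next; d <- d_next; l <- l_next
    dbc <- dbc_next; doth <- doth_next
  }

  flows <- tibble::as_tibble(cbind(cycle = 0:(H - 1), age = ages, fl,
                                   local_recurrences = loc_flow,
                                   distant_recurrences = dist_flow))
  structure(list(states = states, flows = flows, config = config,
                 strategy_kind = strategy$kind),
            class = "bc_trace")
}

#' @export
print.bc_trace <- function(x, ...) {
  H <- nrow(x$flows)
  cat(sprintf(
    "<bc_trace> %s arm | ages %d-%d | cum. BC incidence %.4f | BC deaths %.4f\n",
    x$strategy_kind, x$config$start_age, x$config$horizon_age,
    sum(dplyr::select(x$flows, dplyr::starts_with("diag_"))),
    x$states[H + 1, "dead_bc"]))
  invisible(x)
}

#' Cohort trace as a long tibble
#'
#' @param x A `bc_trace`.
#' @param ... Unused.
#' @return Tibble with columns `cycle`, `age`, `state`, `occupancy`.
#' @method as_tibble bc_trace
#' @export
as_tibble.bc_trace <- function(x, ...) {
  H <- nrow(x$states) - 1
  cyc <- rep(0:H, times = ncol(x$states))
  tibble::tibble(
    cycle = cyc,
    age = x$config$start_age + cyc,
    state = rep(colnames(x$states), each = H + 1),
    occupancy = as.vector(x$states)
  )
}

#' Export a trace as a wide CSV
#'
#' One row per cycle; state-occupancy columns followed by event-flow columns.
#'
#' @param trace A `bc_trace`.
#' @param path Output file path.
#' @return The wide tibble, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  H <- nrow(trace$flows)
  wide <- dplyr::bind_cols(
    tibble::as_tibble(trace$states[seq_len(H), , drop = FALSE]),
    dplyr::select(trace$flows, -"cycle", -"age")
  )
  wide <- dplyr::mutate(wide, cycle = 0:(H - 1),
                        age = trace$config$start_age + cycle, .before = 1)
  readr::write_csv(wide, path)
  invisible(wide)
}
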