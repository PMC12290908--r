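#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an economic summary
#'
#' @param x A `bc_econ` row.
#' @param ... Unused.
#' @return Long tibble with `strategy`, `measure`, `value`.
#' @method tidy bc_econ
#' @export
tidy.bc_econ <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"strategy",
                      names_to = "measure", values_to = "value")
}

#' @rdname tidy.bc_econ
#' @method glance bc_econ
#' @export
glance.bc_econ <- function(x, ...) tibble::as_tibble(x)

#' Tidy an incremental comparison
#'
#' @param x A `bc_icer`.
#' @param ... Unused.
#' @return One-row tibble with `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance`.
#' @method tidy bc_icer
#' @export
tidy.bc_icer <- function(x, ...) {
  tibble::tibble(delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
                 icer = x$icer, dominance = x$dominance)
}

#' @rdname tidy.bc_icer
#' @method glance bc_icer
#' @export
glance.bc_icer <- function(x, ...) tidy.bc_icer(x)

#' Tidy a cohort trace
#'
#' @param x A `bc_trace`.
#' @param ... Unused.
#' @return Long tibble of per-cycle state occupancy.
#' @method tidy bc_trace
#' @export
tidy.bc_trace <- function(x, ...) as_tibble.bc_trace(x)

#' @rdname tidy.bc_trace
#' @method glance bc_trace
#' @export
glance.bc_trace <- function(x, ...) {
  H <- nrow(x$flows)
  tibble::tibble(
    strategy = x$strategy_kind,
    cycles = H,
    cumulative_bc_incidence =
      sum(dplyr::select(x$flows, dplyr::starts_with("diag_"))),
    bc_deaths = x$states[H + 1, "dead_bc"],
    other_deaths = x$states[H + 1, "dead_other"]
  )
}

#' Tidy a probabilistic sensitivity analysis
#'
#' `tidy()` returns the acceptability curve; `glance()` one summary row.
#'
#' @param x A `bc_psa`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bc_psa
#' @export
tidy.bc_psa <- function(x, ...) x$ceac

#' @rdname tidy.bc_psa
#' @method glance bc_psa
#' @export
glance.bc_psa <- function(x, ...) {
  tibble::tibble(
    n = x$n, seed = x$seed, n_redraws = x$n_redraws,
    lifetime_risk = x$lifetime_risk, start_age = x$start_age,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qaly = mean(x$draws$delta_qaly),
    median_icer = stats::median(x$draws$delta_cost / x$draws$delta_qaly)
  )
}
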