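#' Plot a cohort trace
#'
#' Stacked state occupancy over age, tunnels aggregated per stage group.
#'
#' @param object A `bc_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bc_trace
#' @export
autoplot.bc_trace <- function(object, ...) {
  dat <- as_tibble.bc_trace(object)
  dat <- dplyr::mutate(dat, group = dplyr::case_when(
    grepl("_y\\d+$", .data$state) ~ sub("_y\\d+$", "", .data$state),
    TRUE ~ .data$state))
  dat <- dplyr::summarise(dat, occupancy = sum(.data$occupancy),
                          .by = c("age", "group"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$age, .data$occupancy,
                                    fill = .data$group)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Cohort occupancy", fill = NULL,
                  title = sprintf("%s arm", object$strategy_kind))
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object A `bc_psa`.
#' @param ... Unused.
#' @return A ggplot of P(RRM cost-effective) against willingness to pay.
#' @method autoplot bc_psa
#' @export
autoplot.bc_psa <- function(object, ...) {
  ggplot2::ggplot(object$ceac, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (per QALY)",
                  y = "Probability RRM cost-effective",
                  title = sprintf("CEAC: %.0f%% lifetime risk, age %d (n = %d)",
                                  100 * object$lifetime_risk,
                                  object$start_age, object$n))
}

#' Plot a tornado diagram
#'
#' @param object A `bc_tornado` from [owsa()].
#' @param ... Unused.
#' @return A ggplot with one horizontal bar per parameter, widest on top.
#' @method autoplot bc_tornado
#' @export
autoplot.bc_tornado <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       name = stats::reorder(.data$name, .data$spread))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       yend = .data$name), linewidth = 4) +
    ggplot2::geom_vline(xintercept = dat$icer_base[1], linetype = 2) +
    ggplot2::labs(x = "ICER (per QALY)", y = NULL,
                  title = "One-way sensitivity analysis")
}

#' Plot a threshold sweep
#'
#' @param sweep Output of [threshold_sweep()].
#' @return A ggplot of threshold risk against start age, one line per WTP.
#' @export
plot_threshold_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$start_age, .data$threshold_risk,
                                      colour = factor(.data$wtp))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = "Age at surgery (years)",
                  y = "Lifetime-risk threshold for cost-effectiveness",
                  colour = "WTP (per QALY)")
}
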